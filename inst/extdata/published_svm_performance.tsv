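config	TP	FP	TN	FN	TPR	FPR	accuracy
micro_linear	42	17	53	4	0.91	0.24	0.82
micro_poly	39	24	46	7	0.85	0.34	0.73
micro_RBF	37	3	67	9	0.80	0.04	0.90
chip_binary_linear	35	10	60	11	0.78	0.13	0.84
chip_binary_poly	36	5	65	10	0.78	0.07	0.87
chip_binary_RBF	39	8	62	7	0.85	0.11	0.87
chip_contin_linear	38	7	63	8	0.83	0.10	0.87
chip_contin_poly	36	8	62	10	0.78	0.11	0.84
chip_contin_RBF	39	5	65	7	0.85	0.07	0.90
weight_binary_linear	39	9	61	7	0.85	0.13	0.86
weight_binary_poly	37	5	65	9	0.80	0.07	0.88
weight_binary_RBF	40	4	66	6	0.87	0.06	0.91
weight_contin_linear	41	9	61	5	0.89	0.13	0.88
weight_contin_poly	37	8	62	9	0.80	0.11	0.85
weight_contin_RBF	42	5	65	4	0.91	0.07	0.92
simple_binary_linear	39	9	61	7	0.85	0.13	0.86
simple_binary_poly	37	3	67	9	0.80	0.04	0.90
simple_binary_RBF	42	3	67	4	0.91	0.04	0.94
simple_contin_linear	41	9	61	5	0.89	0.13	0.88
simple_contin_poly	43	17	53	3	0.93	0.24	0.83
simple_contin_RBF	41	3	67	5	0.89	0.04	0.93
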