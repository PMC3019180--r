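config	ratio
micro_linear	1.44
micro_poly	1.00
micro_RBF	3.91
chip_binary_linear	1.36
chip_binary_poly	1.84
chip_binary_RBF	1.88
chip_contin_linear	1.57
chip_contin_poly	1.86
chip_contin_RBF	1.91
weight_binary_linear	1.80
weight_binary_poly	1.96
weight_binary_RBF	3.82
weight_contin_linear	1.84
weight_contin_poly	1.65
weight_contin_RBF	2.35
simple_binary_linear	1.80
simple_binary_poly	3.43
simple_binary_RBF	3.80
simple_contin_linear	1.84
simple_contin_poly	1.38
simple_contin_RBF	3.21
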