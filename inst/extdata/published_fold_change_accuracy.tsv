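dataset	accuracy
GSE3223	0.73
GSE10518	0.79
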