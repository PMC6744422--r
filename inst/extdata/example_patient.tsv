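variant_id	PT	LN1	Liver
#roles	primary	lymph_node	distant
chr1_11174372_G_A	1	1	1
chr3_178936091_G_A	1	1	1
chr8_128750540_T_C	1	0	0
chr11_534288_C_T	0	1	1
chr17_7577538_C_T	0	1	1
chr20_57484421_A_G	0	0	1
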