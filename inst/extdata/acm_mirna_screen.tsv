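mirna	dcq_case	dcq_control	p_adj
hsa-miR-520c-3p	29.9	36.7	0.012
hsa-miR-29b-3p	28.6	31.6	0.020
hsa-miR-1183	30.7	34.7	0.040
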