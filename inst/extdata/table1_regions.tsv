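region	total_residues	mutated
whole_protein	1020	213
active_site	30	10
nterm_plp	20	6
h_interface	17	6
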