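mutation	position	ref_aa	alt_aa	ddg_kcal_mol	conservation_grade	blosum62	sec_struct	active_site	active_region_7A	nterm_plp	h_interface	dimer_interface
R515S	515	R	S	-2.47	9	-1	loop	FALSE	FALSE	FALSE	FALSE	FALSE
A389V	389	A	V	0.50	9	0	helix	FALSE	FALSE	FALSE	FALSE	FALSE
A802V	802	A	V	0.80	5	0	loop	FALSE	FALSE	TRUE	FALSE	FALSE
T269M	269	T	M	0.30	4	-1	loop	FALSE	FALSE	FALSE	FALSE	FALSE
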