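gene	label_class	n_total	n_target_predicted_pathogenic	n_target_defect_N	n_target_defect_C
COL4A3	pathogenic	3	3	3	1
COL4A5	pathogenic	6	6	6	3
COL4A3	vus	4	3	0	0
COL4A5	vus	4	2	1	0
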