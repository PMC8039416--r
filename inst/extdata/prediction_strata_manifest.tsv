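source	gene	label_class	n_total	n_target_predicted_pathogenic
FSGS	COL4A3	vus	14	6
FSGS	COL4A4	vus	10	4
FSGS	COL4A5	vus	6	2
gnomAD	COL4A3	unlabeled	851	301
gnomAD	COL4A4	unlabeled	949	306
gnomAD	COL4A5	unlabeled	483	197
ARUP	COL4A5	pathogenic	327	317
ARUP	COL4A5	benign	7	3
ClinVar	COL4A3	pathogenic	16	12
ClinVar	COL4A4	pathogenic	9	9
ClinVar	COL4A5	pathogenic	287	258
ClinVar	COL4A3	benign	6	0
ClinVar	COL4A4	benign	7	0
ClinVar	COL4A5	benign	7	2
LOVD	COL4A3	pathogenic	34	28
LOVD	COL4A4	pathogenic	49	42
LOVD	COL4A5	pathogenic	699	650
LOVD	COL4A3	benign	2	0
LOVD	COL4A4	benign	27	4
LOVD	COL4A5	benign	6	0
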