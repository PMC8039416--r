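gene	n_total	n_rare_missense	n_rare_stopgain	n_common
COL4A3	29	14	0	15
COL4A4	26	10	1	15
COL4A5	15	6	0	9
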