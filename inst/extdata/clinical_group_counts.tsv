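feature	R	M	CD-L	CD-H
n_cases	17	9	8	12
IgA_aTTG_pos	1	6	8	11
IgA_EmA_pos	1	6	8	12
IgG_aDGL_pos	1	4	6	11
Marsh_3BC	0	1	5	9
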