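#chr	position	description	R1	R2	R3	R4
chr1	1041	TP53_R175H	0.48	0.45	0.22	0.24
chr3	2210	PIK3CA_E545K	0.46	0.00	0.21	0.00
chr7	3377	BRAF_V600E	0.00	0.44	0.00	0.23
chr9	4120	CDKN2A_W110X	0.24	0.00	0.20	0.00
chr12	5980	KRAS_G12D	0.00	0.00	0.19	0.21
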