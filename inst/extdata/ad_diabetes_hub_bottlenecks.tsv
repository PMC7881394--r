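disease	gene	degree	betweenness
AD	CASP3	84	0.017712
AD	BDNF	84	0.022581
AD	GAPDH	129	0.074805
AD	APP	140	0.085575
AD	IGF1	76	0.009626
AD	INS	153	0.099242
AD	CAT	72	0.016219
AD	LEP	73	0.01045
AD	TNF	104	0.025062
AD	IL-6	121	0.032354
AD	APOE	135	0.074739
AD	VEGFA	90	0.020626
AD	TLR4	74	0.016169
AD	CLU	76	0.022463
Diabetes	TNF	103	0.050838
Diabetes	TP53	102	0.094941
Diabetes	CASP3	84	0.027162
Diabetes	PPARG	75	0.029648
Diabetes	CAT	73	0.027995
Diabetes	LEP	75	0.025842
Diabetes	IGF1	75	0.014226
Diabetes	NOS3	71	0.018537
Diabetes	VEGFA	87	0.036401
Diabetes	MAPK1	85	0.03988
Diabetes	MAPK3	101	0.049828
Diabetes	IL-6	101	0.052281
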