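name	gene	direction
Angiogenic	VEGFA	1
Angiogenic	FLT1	1
Angiogenic	KDR	1
Angiogenic	ANGPT1	1
Angiogenic	ANGPT2	1
Angiogenic	PECAM1	1
Angiogenic	VWF	1
Angiogenic	CDH5	1
Angiogenic	TEK	1
Angiogenic	ENG	1
Angiogenic	NOS3	1
Angiogenic	HIF1A	1
Angiogenic	FGF2	1
Angiogenic	PDGFB	1
Angiogenic	PGF	1
Angiogenic	TIE1	1
Angiogenic	ESM1	1
Angiogenic	CD34	1
Angiogenic	EPHB4	1
Angiogenic	DLL4	1
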