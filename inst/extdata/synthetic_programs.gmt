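EMT	synthetic placeholder EMT program (replace with a curated or hallmark EMT set)	VIM	FN1	SNAI1	SNAI2	ZEB1	ZEB2	TWIST1	CDH2	FOXQ1	MMP2
S	synthetic placeholder S-phase program	MCM2	MCM3	MCM4	MCM5	MCM6	PCNA	RRM1	RRM2	GINS2	CDC45
G2M	synthetic placeholder G2M-phase program	MKI67	TOP2A	CCNB1	CCNB2	CDK1	BUB1	AURKA	AURKB	PLK1	CENPF
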