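P53_SIGNALING	p53 signaling pathway (panel members)	TP53	ATM	CHEK2	ATR
WNT_BCATENIN	Wnt/beta-catenin signaling (panel members)	APC	AXIN2	FZD3	CTNNB1	AMER1	TCF7L2	RNF43
ANGIOGENESIS	Angiogenesis (panel members)	APC	CTNNB1	NRAS	PIK3CA	AKT2	BRAF
EGFR_SIGNALING	EGF-receptor signaling (panel members)	KRAS	NRAS	BRAF	PIK3CA	ERBB2	EGFR	ERBB3	MAP2K1
TGFB_SIGNALING	TGF-beta signaling (panel members)	SMAD4	ACVR2A	SMAD2	SMAD3	TGFBR1	TGFBR2
INTERLEUKIN_SIGNALING	Interleukin signaling (panel members)	JAK2	MYC	AKT1	PIK3R1
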