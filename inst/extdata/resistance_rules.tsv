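gene	exon
KRAS	2
KRAS	3
KRAS	4
NRAS	2
NRAS	3
NRAS	4
BRAF	15
PIK3CA	20
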