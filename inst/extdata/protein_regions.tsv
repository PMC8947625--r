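gene	region	start	end
TP53	transactivation	1	63
TP53	proline_rich	64	92
TP53	dna_binding	94	312
TP53	tetramerization	323	356
APC	armadillo	453	767
APC	beta_catenin_binding	1020	1169
APC	beta_catenin_downregulation	1262	2033
APC	basic_domain	2200	2400
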