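gene	position	exon	id	type	hgvs_c	hgvs_p	occ_group	occ_n
PIK3CA	chr3:178916657	2	.	SNP	c.44T>G	p.L15W	CRC	3
PIK3CA	chr3:178916653	2	.	SNP	c.40C>A	p.H14N	CRC	2
PIK3CA	chr3:178916655	2	.	SNP	c.42C>G	p.H14Q	CRC	2
PIK3CA	chr3:178921531	5	.	SNP	c.1013T>A	p.I338N	CP	1
PIK3CA	chr3:178948053	20	.	SNP	c.2825A>G	p.K942R	CRC	1
PIK3CA	chr3:178951937	21	.	SNP	c.2992T>C	p.F998L	CRC	1
FBXW7	chr4:153244235	11	.	SNP	c.1568C>A	p.S523X	CRC	1
FBXW7	chr4:153247195	9	.	INDEL	c.1252dupA	p.T418fs	CRC	1
FBXW7	chr4:153249394	8	.	SNP	c.1030T>C	p.S344P	CRC	1
FBXW7	chr4:153268206	3	.	SNP	c.248C>T	p.P83L	IBD	1
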