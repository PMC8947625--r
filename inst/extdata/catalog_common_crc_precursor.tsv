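gene	position	id	type	class	hgvs_c	hgvs_p	n_ibd	n_cp	n_crc
TP53	chr17:7579433	COSM6970737	INDEL	PV	c.137delC	p.P46fs	1	2	2
TP53	chr17:7572991	COSM6806501	INDEL	VUS	c.722delA	p.K241fs	2	0	2
TP53	chr17:7577121	COSM99933	SNP	CIP/PV#	c.421C>T	p.R141C	0	1	3
TP53	chr17:7577120	COSM1645335	SNP	PV-LPV/PV#	c.422G>A	p.R141H	1	1	1
TP53	chr17:7578263	COSM99666	SNP	PV/PV#	c.190C>T	p.R64X	0	1	1
APC	chr5:112116592	COSM13134	SNP	PV/PV#	c.667C>T	p.R223X	1	0	1
APC	chr5:112173831	COSM201301	INDEL	PV	c.2486delA	p.E829fs	1	0	1
APC	chr5:112175101	COSM19262	INDEL	PV	c.3756delT	p.C1252fs	1	1	0
APC	chr5:112175639	COSM13127	SNP	PV/PV#	c.4294C>T	p.R1432X	0	1	1
APC	chr5:112178690	COSM4169178	SNP	CIP/PV#	c.7345C>A	p.P2449T	0	1	1
ACVR2A	chr2:148657066	COSM5192837	INDEL	VUS	c.303delT	p.Y101fs	0	1	1
KRAS	chr12:25398281	COSM532	SNP	PV/PV#	c.38G>A	p.G13D	1	1	3
KRAS	chr12:25398284	COSM1135366	SNP	PV/PV#	c.35G>A	p.G12D	0	1	3
BRAF	chr7:140453136	COSM476	SNP	PV/PV#	c.1799T>A	p.V600E	1	0	2
MSH6	chr2:48030692	COSM6715812	INDEL	PV	c.2916delT	p.T972fs	0	1	6
POLE	chr12:133220099	COSM1745059	INDEL	VUS	c.4337_4338del	p.V1446fs	2	2	3
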