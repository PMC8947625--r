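gene	position	exon	id	type	class	hgvs_c	hgvs_p	crc_cases	crc_only
ATM	chr11:108205823	55	COSM21829	SNP	VUS/PV#	c.8138G>A	p.R2713K	1	1
ATM	chr11:108236071	63	COSM3733315	SNP	PV#	c.9007A>G	p.N3003D	1	1
ATM	chr11:108181014	39	COSM2110552	SNP	CIP/PV#	c.5890A>G	p.K1964E	2	0
TP53	chr17:7579406	3	COSM2745056	SNP	PV#	c.164C>G	p.S55X	1	1
TP53	chr17:7579433	3	COSM6970737	INDEL	PV	c.137delC	p.P46fs	2	0
SCG5	chr15:32935813	2	COSM700179	SNP	N#	c.20C>G	p.S7C	1	1
SCG5	chr15:32983953	5	COSM4607013	SNP	VUS/PV#	c.532C>T	p.R178X	2	0
AXIN2	chr17:63530088	10	COSM317040	SNP	VUS/PV#	c.2347G>T	p.A783S	1	1
AXIN2	chr17:63534419	5	COSM6979947	SNP	VUS/PV#	c.1102G>A	p.A368T	1	1
EP300	chr22:41523642	4	COSM6566095	SNP	PV#	c.1058G>A	p.R353H	1	1
EP300	chr22:41556727	20	COSM84765	SNP	LPV/PV#	c.3671+1G>A	p:NA	1	1
FGFR3	chr4:1806083	9	COSM4748566	SNP	PV#	c.1102G>A	p.E368K	1	1
FGFR3	chr4:1806220	9	COSM4604190	SNP	PV#	c.1239G>C	p.K413N	1	1
NAV2	chr11:20101669	15	COSM3383386	SNP	PV#	c.2431G>A	p.V811I	1	1
NAV2	chr11:20122686	22	COSM2112039	SNP	PV#	c.3577G>A	p.A1193T	1	1
PIK3CA	chr3:178952102	21	COSM3724544	SNP	PV#	c.3157A>G	p.T1053A	1	1
FBXW7	chr4:153271257	2	COSM7344083	SNP	PV#	c.167A>G	p.H56R	1	1
EGFR	chr7:55268077	18	COSM7327079	SNP	VUS/PV#	c.2116C>T	p.R706X	1	1
AKT2	chr19:40741933	9	COSM5855773	SNP	PV#	c.910C>T	p.R304C	1	1
ARID1A	chr1:27092791	9	COSM5992207	SNP	VUS/PV#	c.2812G>A	p.A938T	1	1
BRCA1	chr17:41228557	12	COSM6943771	SNP	N#	c.4291G>C	p.E1431Q	1	1
BRCA2	chr13:32972525	27	COSM4990374	SNP	CIP/PV#	c.9875C>T	p.P3292L	1	1
DCC	chr18:50936877	20	COSM4072554	SNP	PV#	c.2991G>A	p.M997I	2	1
FZD3	chr8:28384945	4	COSM5979515	INDEL	VUS#	c.674dupT	p.T225fs	1	1
MYC	chr8:128748843	1	COSM6206407	SNP	PV#	c.4G>A	p.D2N	2	1
PMS1	chr2:190670454	3	COSM6938193	SNP	PV#	c.209C>T	p.S70F	1	1
PMS2	chr7:6029533	8	COSM6923151	SNP	VUS/PV#	c.724G>A	p.E242K	1	1
ACVR2A	chr2:148657066	3	COSM5192837	INDEL	VUS	c.303delT	p.Y101fs	2	0
CASP8	chr2:202134265	4	COSM7339941	SNP	N#	c.338C>A	p.A113E	2	0
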