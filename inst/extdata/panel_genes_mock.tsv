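gene	chrom	start	end	n_exons	weight
TP53	chr1	1050000	1060592	11	8
APC	chr2	2050000	2068505	16	7
KRAS	chr3	3050000	3071902	6	4
NRAS	chr4	4050000	4078768	7	1.5
BRAF	chr5	5050000	5075415	18	2
PIK3CA	chr6	6050000	6088704	21	4
POLE	chr7	7050000	7082155	20	3
MSH6	chr8	8050000	8063987	14	3
FBXW7	chr9	9050000	9087905	24	3
SMAD4	chr10	10050000	10059812	9	2.5
ATM	chr11	11050000	11063664	12	2.5
FGFR3	chr12	12050000	12062322	16	2.5
CTNNB1	chr13	13050000	13085870	16	1
AXIN2	chr14	14050000	14084425	25	1
FZD3	chr15	15050000	15081793	14	1
AMER1	chr16	16050000	16083552	14	1
ACVR2A	chr17	17050000	17086422	16	1
EP300	chr18	18050000	18060765	5	1
SCG5	chr19	19050000	19062373	11	1
NAV2	chr20	20050000	20068781	22	1
AKT2	chr21	21050000	21070353	23	1
ARID1A	chr22	22050000	22075119	7	1
BRCA1	chr1	23050000	23062593	12	1
BRCA2	chr2	24050000	24087551	21	1
DCC	chr3	25050000	25081330	15	1
MYC	chr4	26050000	26071779	5	1
PMS1	chr5	27050000	27085255	13	1
PMS2	chr6	28050000	28065326	20	1
CASP8	chr7	29050000	29085189	21	1
EGFR	chr8	30050000	30083144	19	1
ERBB2	chr9	31050000	31071448	9	1
MLH1	chr10	32050000	32075065	12	1
MSH2	chr11	33050000	33058326	23	1
EPCAM	chr12	34050000	34082317	8	1
MUTYH	chr13	35050000	35082803	15	1
STK11	chr14	36050000	36065307	23	1
PTEN	chr15	37050000	37087011	20	1
BMPR1A	chr16	38050000	38089175	20	1
SMAD2	chr17	39050000	39085403	17	1
SMAD3	chr18	40050000	40059300	8	1
TGFBR1	chr19	41050000	41066910	5	1
TGFBR2	chr20	42050000	42065707	11	1
TCF7L2	chr21	43050000	43081184	25	1
SOX9	chr22	44050000	44076140	14	1
GNAS	chr1	45050000	45070827	10	1
ERBB3	chr2	46050000	46083559	21	1
ERBB4	chr3	47050000	47059720	7	1
MAP2K1	chr4	48050000	48084138	17	1
MAP2K4	chr5	49050000	49084517	18	1
RNF43	chr6	50050000	50085019	22	1
POLD1	chr7	51050000	51073695	21	1
CDKN2A	chr8	52050000	52064968	23	1
CHEK2	chr9	53050000	53058065	13	1
CDC73	chr10	54050000	54073205	6	1
AKT1	chr11	55050000	55070411	16	1
AKT3	chr12	56050000	56066746	7	1
MTOR	chr13	57050000	57062666	5	1
RICTOR	chr14	58050000	58064415	10	1
NF1	chr15	59050000	59086241	23	1
RB1	chr16	60050000	60076880	23	1
VHL	chr17	61050000	61088946	13	1
KIT	chr18	62050000	62083578	22	1
PDGFRA	chr19	63050000	63072935	23	1
FLT3	chr20	64050000	64077484	5	1
JAK2	chr21	65050000	65078112	15	1
NOTCH1	chr22	66050000	66064078	19	1
NOTCH2	chr1	67050000	67071946	23	1
FAT4	chr2	68050000	68073848	19	1
LRP1B	chr3	69050000	69080967	23	1
GRIN2A	chr4	70050000	70081223	10	1
TRRAP	chr5	71050000	71084554	16	1
KMT2C	chr6	72050000	72072775	15	1
KMT2D	chr7	73050000	73084148	19	1
ARID2	chr8	74050000	74065526	25	1
SMARCA4	chr9	75050000	75079679	15	1
ATR	chr10	76050000	76081303	10	1
ATRX	chr11	77050000	77068447	22	1
PALB2	chr12	78050000	78066329	24	1
RAD50	chr13	79050000	79067295	11	1
RAD51	chr14	80050000	80089000	8	1
NBN	chr15	81050000	81068496	18	1
BLM	chr16	82050000	82086978	23	1
WRN	chr17	83050000	83087813	15	1
EXO1	chr18	84050000	84080529	5	1
POLQ	chr19	85050000	85062896	5	1
TET2	chr20	86050000	86071074	20	1
DNMT3A	chr21	87050000	87080594	18	1
IDH1	chr22	88050000	88067349	22	1
IDH2	chr1	89050000	89064053	20	1
HRAS	chr2	90050000	90062970	10	1
RAF1	chr3	91050000	91085968	15	1
MAP3K1	chr4	92050000	92077205	24	1
PIK3R1	chr5	93050000	93086768	7	1
INPP4B	chr6	94050000	94076264	9	1
FBXO11	chr7	95050000	95079033	10	1
CYLD	chr8	96050000	96083796	22	1
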