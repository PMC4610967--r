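locus	allele	observed_motif	category	coverage	AFA	CAU	HIS	variant_type	haplogroups
DYS389I	9	[TCTA]9	nominal	60	0	1	0	RPV	R1b
DYS389II	29	[TCTG]6[TCTA]10 N48 [TCTG]3[TCTA]10	nominal	25	0	0	1	RPV	E1b1b
DYS389II	29	[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]9	nominal	6	1	0	0	RPV	E1b1a
DYS389II	30	[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]10	nominal	5-29	1	0	0	RPV	E1b1a
DYS389II	31	[TCTG]6[TCTA]11 N48 [TCTG]3[TCTA]11	nominal	8	0	1	0	RPV	E1b1a
DYS389II	32	[TCTG]6[TCTA]13 N48 [TCTG]3[TCTA]10	nominal	6	1	0	0	RPV	E1b1b
DYS390	21	[TCTG]8[TCTA]8[TCTG]1[TCTA]4	nominal	18-188	1	0	0	RPV	E1b1a
DYS390	21	[TCTG]8[TCTA]9[TCTG]1[TCTA]3	nominal	72	1	0	0	RPV	E1b1b
DYS393	13	[CGAT]1[AGAT]12	nominal	59	0	1	0	A/C SNP	R1a
DYS481	25	[CTG]1[CTT]24	nominal	413	0	1	0	T/G SNP	I2a
DYS481	26	[CTG]1[CTT]25	nominal	211	0	1	0	T/G SNP	E1b1a
DYS518	36	[AAAG]3[GAAG]1[AAAG]14[GGAG]1[AAAG]4 N6 [AAAG]13	nominal	31	0	0	1	RPV	G2a
DYS518	37	[AAAG]3[GAAG]1[AAAG]16[GGAG]1[AAAG]4 N6 [AAAG]12	nominal	13	0	1	0	RPV	R1b
DYS518	38	[AAAG]3[GAAG]1[AAAG]14[GGAG]1[AAAG]4 N6 [AAAG]15	nominal	44	0	0	1	RPV	J2a
DYS518	38	[AAAG]3[GAAG]1[AAAG]15[GGAG]1[AAAG]4 N6 [AAAG]14	nominal	10-68	2	2	1	RPV	E1b1a, I2a, J2b, R1b
DYS518	39	[AAAG]3[GAAG]1[AAAG]18[GGAG]1[AAAG]4 N6 [AAAG]12	nominal	26	0	0	1	RPV	I2b
DYS518	40	[AAAG]3[GAAG]1[AAAG]18[GGAG]1[AAAG]4 N6 [AAAG]13	nominal	22	1	0	0	RPV	E1b1a
DYS518	41	[AAAG]3[GAAG]1[AAAG]16[GGAG]1[AAAG]4 N6 [AAAG]16	nominal	22	0	1	0	RPV	R1a
DYS635	23	[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]3[TCTA]8	nominal	247	0	0	1	RPV	R1b
DYS449	25	[TTTC]11 N50 [TTTC]14	novel	10	0	0	1	RPV	J1
DYS505	11	[TCCT]11	novel	28-55	1	2	5	RPV	E1b1b, G2a, I1, O/Q, R1b
DYS505	14	[TCCT]14	novel	24	1	0	0	RPV	E1b1a
DYS533	9	[ATCT]9	novel	113	0	0	1	RPV	G2a
DYS533	11	[ATCT]11	novel	8-629	4	5	4	RPV	E1b1a, E1b1b, I1, J2a, O/Q, R1b
DYS533	13	[ATCT]13	novel	83-458	1	1	2	RPV	R1b
DYS533	14	[ATCT]14	novel	129	0	1	0	RPV	R1b
DYS549	10	[GATA]10	novel	362-402	1	1	0	RPV	E1b1a, I2a
DYS549	11	[GATA]11	novel	15-390	5	0	1	RPV	E1b1a, E1b1b
DYS570	23	[TTTC]5[TCTC]1[TTTC]17	novel	192	0	0	1	T/C SNP	E1b1b
DYS576	13	[AAAG]13	novel	360	1	0	0	RPV	E1b1a
DYS576	22	[AAAG]22	novel	149	0	0	1	RPV	R1b
DYS612	35	[CCT]5[CTT]1[TCT]4[CCT]1[TCT]17[CCT]1[TCT]12	novel	122	0	0	1	T/C SNP	J2b
DYS635	24	[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]2[TCTA]10	novel	9	1	0	0	RPV	R1b
DYS635	25	[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]2[TCTA]11	novel	23-28	0	1	0	RPV	R1b
DYS635	26	[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]2[TCTA]12	novel	13	1	0	0	RPV	R1b
DYS643	8	[CTTTT]8	novel	395	0	0	1	RPV	J2a
DYS643	14	[CTTTT]14	novel	34	1	0	0	RPV	E1b1a
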