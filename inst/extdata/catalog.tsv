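locus	allele	decomposition	source	snp
DYS389I	9	[TCTG]3[TCTA]6	strbase
DYS389II	29	[TCTG]5[TCTA]11 N48 [TCTG]3[TCTA]10	synthetic
DYS389II	30	[TCTG]5[TCTA]12 N48 [TCTG]3[TCTA]10	synthetic
DYS389II	31	[TCTG]5[TCTA]12 N48 [TCTG]3[TCTA]11	synthetic
DYS389II	32	[TCTG]5[TCTA]13 N48 [TCTG]3[TCTA]11	synthetic
DYS390	21	[TCTG]7[TCTA]9[TCTG]1[TCTA]4	synthetic
DYS393	13	[AGAT]13	synthetic
DYS481	21	[CTG]1[CTT]20	literature	T/G
DYS481	25	[CTT]25	synthetic
DYS481	26	[CTT]26	synthetic
DYS518	36	[AAAG]3[GAAG]1[AAAG]15[GGAG]1[AAAG]4 N6 [AAAG]12	synthetic
DYS518	37	[AAAG]3[GAAG]1[AAAG]15[GGAG]1[AAAG]4 N6 [AAAG]13	synthetic
DYS518	38	[AAAG]3[GAAG]1[AAAG]16[GGAG]1[AAAG]4 N6 [AAAG]13	synthetic
DYS518	39	[AAAG]3[GAAG]1[AAAG]17[GGAG]1[AAAG]4 N6 [AAAG]13	synthetic
DYS518	40	[AAAG]3[GAAG]1[AAAG]17[GGAG]1[AAAG]4 N6 [AAAG]14	synthetic
DYS518	41	[AAAG]3[GAAG]1[AAAG]17[GGAG]1[AAAG]4 N6 [AAAG]15	synthetic
DYS635	23	[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]2[TCTA]9	synthetic
DYS385	13.2	[GAAA]13+GA	literature
DYS458	17.2	[GAAA]17+GA	literature
DYS19	14	[TAGA]14	synthetic
DYS391	10	[TCTA]10	synthetic
DYS392	13	[TAT]13	synthetic
DYS437	15	[TCTA]15	synthetic
DYS438	10	[TTTTC]10	synthetic
DYS439	12	[GATA]12	synthetic
DYS448	19	[TAGGA]19	synthetic
DYS449	28	[TTTC]13 N50 [TTTC]15	synthetic
DYS456	15	[AGAT]15	synthetic
DYS460	10	[ATAG]10	synthetic
DYS505	12	[TCCT]12	synthetic
DYS522	12	[GATA]12	synthetic
DYS533	12	[ATCT]12	synthetic
DYS549	12	[GATA]12	synthetic
DYS570	17	[TTTC]17	synthetic
DYS576	17	[AAAG]17	synthetic
DYS612	36	[CCT]5[CTT]1[TCT]4[CCT]1[TCT]31	synthetic
DYS635	21	[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]2[TCTA]7	synthetic
DYS643	10	[CTTTT]10	synthetic
GATA-H4	12	[TAGA]12	synthetic
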