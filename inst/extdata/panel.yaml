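# Panel configuration: 28 forensically relevant Y-STR loci.
#
# Reference repeat motifs use the bracket dialect ([UNIT]count, symbolic
# n/p/q/r for variable blocks, N<len> spacers). Flank anchors and spacer
# fill sequences are fixed synthetic fixtures: they were drawn once at
# random (16 nt anchors) and verified to occur nowhere in any realizable
# amplicon of the panel other than at their own locus, so that exact
# anchored extraction is unambiguous on simulated data. Spacer content is
# treated as opaque everywhere; only its length matters.
#
# counted_blocks lists, per repeat block, whether the block contributes
# to the nominal allele designation ("all" = every block counts). The
# DYS612 mask excludes the leading [CCT]5[CTT]1 blocks, the only
# assignment consistent with its conventional allele numbering.
#
# sim_counts gives, per variable block, the [lo, hi] repeat-count range
# the read simulator draws from; ranges are chosen so every realizable
# amplicon fits inside one 250 nt read. mean_coverage is the default
# simulated read-pair count per locus, spanning the 9-387x range typical
# of capture-based Y-STR sequencing.
loci:
- name: DYS19
  period: 4
  motif: "[TAGA]n"
  flank5: AATGTGAGTGCACCTA
  flank3: ACTTTACCCAGCAATC
  sim_counts: [[11, 16]]
  mean_coverage: 150
- name: DYS385
  period: 4
  motif: "[GAAA]n"
  flank5: TGCGTGAATACGGGTC
  flank3: TCGATTCGCCGGACCG
  multicopy: true
  sim_counts: [[11, 18]]
  mean_coverage: 120
- name: DYS389I
  period: 4
  motif: "[TCTG]3[TCTA]n"
  flank5: TTATCGAAAGATACGC
  flank3: TGATGTACCGGGGCCC
  sim_counts: [[6, 11]]
  mean_coverage: 180
- name: DYS389II
  period: 4
  motif: "[TCTG]n[TCTA]pN48[TCTG]3[TCTA]q"
  flank5: TTATAGAGAAAGGTGG
  flank3: ACGCCTATGTACAGGC
  spacer_fills: [GCAACGTACCTTTGGGCACCGGCACACTTTACGGCGCGGGCAGATGGA]
  sim_counts: [[5, 7], [9, 13], [9, 12]]
  mean_coverage: 37
- name: DYS390
  period: 4
  motif: "[TCTG]8[TCTA]n[TCTG]1[TCTA]4"
  flank5: CGGAGGGTGATTCCTC
  flank3: TATTGCTACGACTGGG
  sim_counts: [[7, 12]]
  mean_coverage: 210
- name: DYS391
  period: 4
  motif: "[TCTA]n"
  flank5: AATAAACGCCGAAAGT
  flank3: GTTCCAGCGTGCCTAT
  sim_counts: [[9, 13]]
  mean_coverage: 333
- name: DYS392
  period: 3
  motif: "[TAT]n"
  flank5: ACAGAGGCCGCCCCTT
  flank3: GTGAGTTTCGCGGTCC
  sim_counts: [[11, 16]]
  mean_coverage: 160
- name: DYS393
  period: 4
  motif: "[AGAT]n"
  flank5: CTTCGACATGATCACT
  flank3: GGGATGCATAGGCCTC
  sim_counts: [[11, 16]]
  mean_coverage: 140
- name: DYS437
  period: 4
  motif: "[TCTA]n"
  flank5: GTGCCGGAACGGGTAT
  flank3: TTCCCAAAGTACGTAA
  sim_counts: [[13, 17]]
  mean_coverage: 190
- name: DYS438
  period: 5
  motif: "[TTTTC]n"
  flank5: TGTAGATAGACATCGT
  flank3: GATGTTCCTAGCAGTT
  sim_counts: [[8, 13]]
  mean_coverage: 387
- name: DYS439
  period: 4
  motif: "[GATA]n"
  flank5: GCTGCTTTACGGTTTT
  flank3: AGGCCTTCCCTTACGC
  sim_counts: [[10, 14]]
  mean_coverage: 170
- name: DYS448
  period: 5
  motif: "[TAGGA]n"
  flank5: TTACTGTCATGGTCGT
  flank3: TACTAAGATATTGTAG
  sim_counts: [[17, 22]]
  mean_coverage: 9
- name: DYS449
  period: 4
  motif: "[TTTC]nN50[TTTC]p"
  flank5: CATACGGTCGAAATCC
  flank3: GGTCGCAGCTTCGGTA
  spacer_fills: [GATCGTGGACAGTAAGGCACAGGAGTACGTTCTGATGCTTATTAGAAATT]
  sim_counts: [[11, 16], [12, 17]]
  mean_coverage: 33
- name: DYS456
  period: 4
  motif: "[AGAT]n"
  flank5: ATTGCCCATCAACGTT
  flank3: GAGAGCCCCCGTCCTT
  sim_counts: [[13, 17]]
  mean_coverage: 130
- name: DYS458
  period: 4
  motif: "[GAAA]n"
  flank5: TAGTCGTACGACCTAA
  flank3: GCGTGACAGTAGTGAG
  sim_counts: [[14, 19]]
  mean_coverage: 110
- name: DYS460
  period: 4
  motif: "[ATAG]n"
  flank5: TGGTTCAAGGGCGATT
  flank3: CAATGATTAGTTAGTA
  sim_counts: [[9, 12]]
  mean_coverage: 200
- name: DYS481
  period: 3
  motif: "[CTT]n"
  flank5: ACTCATCCCCACATAT
  flank3: GCATCAAATTCCAGTG
  sim_counts: [[20, 28]]
  mean_coverage: 240
- name: DYS505
  period: 4
  motif: "[TCCT]n"
  flank5: CGGAAAATTGATATGA
  flank3: TGTCAATAGAAAGCAC
  sim_counts: [[9, 14]]
  mean_coverage: 38
- name: DYS518
  period: 4
  motif: "[AAAG]3[GAAG]1[AAAG]n[GGAG]1[AAAG]4N6[AAAG]p"
  flank5: TTCGTGCCTTGTTTAT
  flank3: TTAGCGATCACATAAA
  spacer_fills: [TTCGTG]
  sim_counts: [[13, 18], [11, 16]]
  mean_coverage: 34
- name: DYS522
  period: 4
  motif: "[GATA]n"
  flank5: TACTGCAACGGCGTAC
  flank3: ACCTGTGACCCATAGG
  sim_counts: [[10, 14]]
  mean_coverage: 90
- name: DYS533
  period: 4
  motif: "[ATCT]n"
  flank5: CAGAGTTCCACTCCAA
  flank3: TTTACACGAACGCGAT
  sim_counts: [[9, 14]]
  mean_coverage: 260
- name: DYS549
  period: 4
  motif: "[GATA]n"
  flank5: GTTCCAGAAATGCTAC
  flank3: CCGGAGAACGTACACC
  sim_counts: [[10, 14]]
  mean_coverage: 220
- name: DYS570
  period: 4
  motif: "[TTTC]n"
  flank5: GGTCTATAACGCCATA
  flank3: TGAGTGTTGCTAGTAA
  sim_counts: [[16, 22]]
  mean_coverage: 180
- name: DYS576
  period: 4
  motif: "[AAAG]n"
  flank5: TCTGGAGAGGGGCCCT
  flank3: GACTTGCAGGCGGTGG
  sim_counts: [[13, 22]]
  mean_coverage: 150
- name: DYS612
  period: 3
  motif: "[CCT]5[CTT]1[TCT]4[CCT]1[TCT]n"
  flank5: TGAATCACTAGACTCG
  flank3: GGAGAATACTGTTAAG
  counted_blocks: [false, false, true, true, true]
  sim_counts: [[25, 32]]
  mean_coverage: 70
- name: DYS635
  period: 4
  motif: "[TCTA]4[TGTA]2[TCTA]2[TGTA]2[TCTA]2[TGTA]n[TCTA]p"
  flank5: GGAAAACCGGAACTTG
  flank3: GGCCCAGTATCACCAC
  sim_counts: [[2, 3], [7, 12]]
  mean_coverage: 120
- name: DYS643
  period: 5
  motif: "[CTTTT]n"
  flank5: CCGACGCGAGAGCAAA
  flank3: ACATTCCATCCCTGAA
  sim_counts: [[8, 14]]
  mean_coverage: 322
- name: GATA-H4
  period: 4
  motif: "[TAGA]n"
  flank5: TTTTCTCGTTCATCGG
  flank3: GATGATCGGAGACCTC
  sim_counts: [[10, 14]]
  mean_coverage: 100
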