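seq,tm
CCCTCACCCGAT,37.719657
GCCTATCAGCTATTAGA,40.479314
CAAGAAATCCGTTAGGGAT,46.211913
GGGGCCCAGTCCAGACG,56.090450
AGCCTTATCGGAAAACCCAAAGGTGA,58.454222
GACACATTGATACCACTTGGCTAATGG,56.300416
GCTATTCACGGGTTGTTTCAGCAGCCGGTGTTCCATTGC,69.188168
TCGAGCTGGGGTAG,43.640725
GATTGGCTACAATTGATATCG,46.956562
GAGTCTGGCCTAGTTAGTT,47.378488
CCCGTATCGTCAATTCCACAGTTAAA,55.629087
GATAGTTCCTATTCTGTTATGTCCACAGAA,54.757032
ACTGGGATCCTAGTGGGCAA,54.198955
CTAGCTTCACT,24.115608
TAGTGCATTTGCTATGTCTGGAAACCAACATGT,60.732096
GGGCGATTCTGGACGGTTAACTTAG,57.498002
TTTCTGGAACAGAC,35.678283
CACGGTGTCCTCATCAT,47.620734
CGCCTAGCAGGATACC,47.277624
TGTGCGTGTAATGTA,39.945791
ACGAGGGGTTCCTGATTTCTGCGTTGTAC,62.306810
TATCTCGAAAGCTGATCGGTGTCTGACCTTCTCCACTGAG,66.240177
ATAATCTTTGTGGCGAATGTCTTTAATCGGA,57.548689
GCCGTGCCCTGAAGGTCTCCCCCTTCCCGGGGGACAGC,76.107233
AGACCTATGCCCTTCCGA,50.979802
TCTAAAGTATTAGAC,28.780557
ATTGACAGTACTT,28.078928
GTCCGCCGGCTACCGTTCTCAC,61.722632
GCGTGTATGC,28.105444
TCCTGCTCGTGGGGACTAT,53.749588
CCGCGTAACCCCGGATTTTGCC,60.925188
GGTGGGAAGCGCGTTTCT,54.996598
ATTCCAACGAAAATGGTACGCTATTGCTTTATTCAG,60.166246
TTGTAGATAGAAATCAACT,39.717895
GAGCAGTGTGAATCGAT,45.742006
TACTGATTTCTGGGGAGATTTTTCGGCTCCTATTGA,61.977956
TGAGCTGCCCCA,41.213271
ATGCGCTATCGCTCGTAGTTGCCCGTTTTATGGG,66.597922
AAGACTGTGGTGGAGCA,49.197371
ATGTTATCTGCCATGAACTCTGTCAATGCGA,60.490092
TGCCGGCATGAAGTTTTGCTGCCATAGCTA,64.325526
TATGACCTGGGGC,39.198603
GGAGAGCGCGGGCGTCC,60.185391
CAACTATGGCCCATTGAGT,49.023173
GCTGTCCGTTAATACTATAAAATCGATTTGT,54.935337
TTGCCGTCCGACAACTTGGTCTGCGGTGCGCCCAAA,72.955024
GCCTCTAGCATGGCACTACAGATTGTGGGCGGTC,67.658068
ATCAGTTAACCCTCGGTCAGAGATACTGAGGTTAT,60.996245
CTTGAATTACGAACTAATCTTTCAACACTGCGAATGT,60.089893
CGTTAACCTCTTTCACA,42.976325
AATTGAGCCCTGTCC,43.212102
AGGTTAAGACGTGCCGTTCACATCCTGGACTCT,65.181910
AGCAGAGATCATGC,39.192037
GTAGTCCACTTACTGTTTCCGATTTCTATG,55.893382
TACTGTACTGTTGTGTGTTCAC,50.519304
TTGACTCCGAGAA,35.028234
AACAGAACTACAATCGTCCTGCAC,55.458094
GGATCACGGTATT,33.318942
CCTGCGGGGGGGAGCTCGGGCGCCAAACCACCGGTCGCTA,78.907130
AACTATGCTGCGCACT,47.623643
ATGCTACGCTTTCGGAGACGCCCAT,62.526001
GACTGACTCTAAGTTCTATGAGAGAAC,52.693957
GTCTGCTAGAAGATACTTGAATGTCAAAC,54.694289
TCGGCAGCGTCATTACCAAGAACTGGCCTCAGTATGCGA,69.616817
TCAATTATCTTCCCGGGTAATCCAATCATTCCATGGAA,62.123388
GAACGAACGC,29.030732
AATGCGCCGCCCCACACGAATCGATCTGGAGATTTATCGA,69.633551
CTGTCGTACACGCGAAGTTTGGGGCAA,63.490686
AAGTCAATCGTCTGGTCGGGATCACCGC,63.961888
GTTCTCTGATCCTCTAA,40.198775
TCAGTTCATAGTGT,33.050166
GCGGTGTGATGCCCCCGGAATGAATTACTGT,65.600331
TGAAAGCAGATATGTCACGAAGGCTGC,59.654206
GGTTAGCTCCCACATAGTTA,48.030320
CACGCTCGCCTCTTTCA,51.720273
TAGCTGATTACGAGCG,44.468161
CGGCAGTGATAATCCC,45.376502
CGTTGAGTCTCATAC,38.358337
TCAGGACGTTTTACGTGCTCGGGAACGTAAATGG,65.002330
GGCACATG,13.645422
AGCAAGGGAGTATTTACTCAGGCGACGATGATAACACGA,65.484443
GTGTTGACCGAGCGGTGGTGATAAGACTACGCAAACAG,67.178215
TAAATCCTTTTCTCGGGAGACCTCGAGTATCCT,61.220153
GTTGAGGATTTCT,30.069118
GTGCCGGTAGCTACTTTAGAACTAAATTTGCAATCGAG,62.415125
GTGGTATTACGCCCCCGAGATCAACAGACTA,62.506578
TCTTCTGAACGAGTTC,41.309758
ATCTAAGCCTAATCACCTGCCATCCCTACTG,60.775645
AGAGCTGTAGCAATTAGTG,46.360610
GGCATGCGC,31.060859
CCCTACTATGGCCGGCACGCCCT,64.356391
AAGACAGCCTAGAGGT,43.841605
GTCTCAGGGTTGCGATGCGTCACCATGTAACG,65.897078
CCTGCACCATTTTAGACAGTGTTTACTTG,57.067106
CCGTCGAAGAGA,35.257668
GGCGTTACGTTGCATTT,48.323234
CCTAATCACGAG,29.159261
GGGGCCCTACCTTAAGTAGCAAAGCTTCCGACGGATCT,68.239493
CCTCTACCAAGGTACAGGCAGGCAGTGACATAACTC,65.038088
GGTGGACCTACCTAATGAAGCCTATAG,55.863674
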