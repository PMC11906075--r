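row	name	sequence	purpose
1	cpBfpE_L1f	ggttctccaggttctACTTTATCTCGTTGGACTGGTCGTTTA	del/ins; delete L0 and add L1
2	cpBfpE_L1r	TagaacctggagaaccTTTAACTTTTTTTTTAGTATCATTCATATAAATAATATCATCTAAAGC	del/ins; delete L0 and add L1
3	cpBfpE_L2f	tctccaggtccaagcggtACTTTATCTCGTTGGACTGGTCGTTTA	del/ins; delete L0 and add L2
4	cpBfpE_L2r	cgcttggacctggagaaccTTTAACTTTTTTTTTAGTATCATTCATATAAATAATATCATCTAAAGC	del/ins; delete L0 and add L2
5	cpBfpE_L3f	ggtggcggtggttctACTTTATCTCGTTGGACTGGTCGTTTA	del/ins; delete L0 and add L3
6	cpBfpE_L3r	TagaaccaccgccaccTTTAACTTTTTTTTTAGTATCATTCATATAAATAATATCATCTAAAGC	del/ins; delete L0 and add L3
7	cpBfpE_L4f	gttctgctgctggttctggtgaattcACTTTATCTCGTTGGACTGGTCGTTTA	del/ins; delete L0 and add L4
8	cpBfpE_L4r	gaaccagcagcagaaccagcagaaccTTTAACTTTTTTTTTAGTATCATTCATATAAATAATATCATCTAAAGC	del/ins; delete L0 and add L4
9	cpE_L0_del_187-211_F	GTTCTGGTACTATTATTGGTTGTGGTTTTTTATTATCTTTAGCT	delete T143-K165 in cpBfpE
10	cpE_L0_del_187-211_R	ATAATAGTACCAGAACCAGAACCAGAACCTTTAAC	delete T143-K165 in cpBfpE
11	cpE_C-His_F	AAATGACTCTCGAGCACCACCACCACCACCACTG	del; delete the stop codon after C-term T272
12	cpE_C-His_R	TGCTCGAGAGTCATTTGTTTAGTAATATAAGCAACAGAATCA	del; delete the stop codon after C-term T272
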