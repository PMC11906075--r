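name	sequence	protein
L1	ggt tct cca ggt tct	GSPGS
L2	ggt tct cca ggt cca agc ggt	GSPGPSG
L3	ggt ggc ggt ggt tct	GGGGS
L4	ggt tct gct ggt tct gct gct ggt tct ggt gaa ttc	GSAGSAAGSGEF
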