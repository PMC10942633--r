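peptide	pre_reduction	post_reduction	percent_redundant
All	619	467	24.56
GILGFVFTL	136	58	57.35
NLVPMVATV	69	54	21.74
YLQPRTFLL	67	53	20.90
TTDPSFLGRY	49	47	4.08
LLWNGPMAV	47	44	6.38
CINGVCWTV	46	46	0.00
GLCTLVAML	37	23	37.84
ATDALMTGF	26	22	15.38
LTDEMIAQY	25	23	8.00
SPRWYFYYL	24	24	0.00
KSKRTPMGF	22	13	40.91
NQKLIANQF	15	15	0.00
TPRVTGGGAM	12	12	0.00
HPVTKYIM	12	10	16.67
NYNYLYRLF	12	9	25.00
GPRLGVRAT	11	11	0.00
RAQAPPPSW	9	3	66.67
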