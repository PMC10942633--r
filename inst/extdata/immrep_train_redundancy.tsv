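peptide	pre_reduction	post_reduction	percent_redundant
All	2445	1960	19.8
GILGFVFTL	544	301	44.7
NLVPMVATV	274	242	11.7
YLQPRTFLL	267	227	15.0
TTDPSFLGRY	193	187	3.1
LLWNGPMAV	188	175	6.9
CINGVCWTV	183	179	2.2
GLCTLVAML	146	91	37.7
ATDALMTGF	104	78	25.0
LTDEMIAQY	100	94	6.0
SPRWYFYYL	92	92	0.0
KSKRTPMGF	85	63	25.9
NQKLIANQF	56	53	5.4
HPVTKYIM	48	41	14.6
TPRVTGGGAM	45	44	2.2
NYNYLYRLF	44	42	4.6
GPRLGVRAT	40	37	7.5
RAQAPPPSW	36	14	61.1
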