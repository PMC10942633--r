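peptide	organism	mhc	pre_reduction	removed_step1	removed_step2	post_reduction	not_10x	from_10x
GILGFVFTL	Influenza A virus	HLA-A*02:01	1897	645	127	1125	426	699
RAKFKQLL	Epstein Barr virus	HLA-B*08:01	1065	114	17	934	0	934
KLGGALQAK	Human CMV	HLA-A*03:01	912	8	2	902	0	902
AVFDRKSDAK	Epstein Barr virus	HLA-A*11:01	725	5	4	716	0	716
ELAGIGILTV	Melanoma neoantigen	HLA-A*02:01	435	6	3	426	55	371
NLVPMVATV	Human CMV	HLA-A*02:01	384	43	11	330	154	176
IVTDFSVIK	Epstein Barr virus	HLA-A*11:01	323	13	2	308	0	308
LLWNGPMAV	Yellow fever virus	HLA-A*02:01	322	72	21	229	229	0
CINGVCWTV	Hepatitis C virus	HLA-A*02:01	231	4	1	226	75	151
GLCTLVAML	Epstein Barr virus	HLA-A*02:01	278	59	7	212	95	117
SPRWYFYYL	SARS-CoV2	HLA-B*07:02	158	4	5	149	149	0
ATDALMTGF	Hepatitis C virus	HLA-A*01:01	128	21	4	103	0	103
DATYQRTRALVR	Influenza A virus	HLA-A*68:01	100	4	3	93	93	0
KSKRTPMGF	Hepatitis C virus	HLA-B*57:01	115	14	12	89	0	89
YLQPRTFLL	SARS-CoV2	HLA-A*02:01	69	6	1	62	54	8
HPVTKYIM	Hepatitis C virus	HLA-B*08:01	60	5	2	53	0	53
RFPLTFGWCF	HIV-1	HLA-A*24:02	58	7	0	51	51	0
GPRLGVRAT	Hepatitis C virus	HLA-B*07:02	51	3	0	48	0	48
CTELKLSDY	Influenza A virus	HLA-A*01:01	48	0	0	48	48	0
RLRAEAQVK	Epstein Barr virus	HLA-A*03:01	47	0	0	47	0	47
RLPGVLPRA	AML neoantigen	HLA-A*02:01	43	0	0	43	0	43
SLFNTVATLY	HIV-1	HLA-A*02:01	38	0	0	38	0	38
RPPIFIRRL	Epstein Barr virus	HLA-B*07:02	40	2	2	36	24	12
FEDLRLLSF	Influenza A virus	HLA-B*37:01	31	0	0	31	31	0
VLFGLGFAI	T1D neoantigen	HLA-A*02:01	32	1	0	31	31	0
FEDLRVLSF	Influenza A virus	HLA-B*37:01	36	0	13	23	23	0
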