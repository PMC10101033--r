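pair_id	fwd_id	fwd_seq	rev_id	rev_seq	domain_scope	most_used	alc	region	ecoli_f_first	ecoli_f_last	ecoli_r_first	ecoli_r_last	length_printed	template_f_first	template_f_last	template_r_first	template_r_last
KP_F048-OP_R043	KP_F048	TACGGRAGGCAGCAG	OP_R043	CCGCGRCTGCTGGCAC	bacteria	FALSE	S	V3-V4	342	356	514	529	187	342	356	514	529
OP_F098-OP_R119	OP_F098	CCAGCAGCYGCGGTAAN	OP_R119	GGACTACCRGGGTATCTAA	bacteria	FALSE	S	V4-V5	517	533	787	805	288	517	533	787	805
OP_F066-KP_R040	OP_F066	GGMTTAGATACCC	KP_R040	CCGTCAATTCMTTTGAGTTT	bacteria	FALSE	S	V5-V6	784	796	906	925	141	784	796	906	925
OP_F009-OP_R030	OP_F009	GGATTAGATACCCBRGTAGTC	OP_R030	TCACRRCACGAGCTGWCGAC	bacteria	FALSE	S	V5-V7	784	804	1060	1079	295	784	804	1060	1079
KP_F061-KP_R074	KP_F061	ACTCAAAKGAATWGACGG	KP_R074	GGGTYKCGCTCGTTR	bacteria	FALSE	S	V6-V7	908	925	1099	1113	205	908	925	1099	1113
OP_F101-OP_R030	OP_F101	GAATTGRCGGGGRCC	OP_R030	TCACRRCACGAGCTGWCGAC	bacteria	FALSE	S	V6-V7	916	930	1060	1079	163	916	930	1060	1079
OP_F053-KP_R020	OP_F053	GRGTTYGATYMTGGCTCAG	KP_R020	CTGCTGCCTYCCGTA	bacteria	FALSE	M	V1-V3	9	27	342	356	347	9	27	342	356
KP_F048-KP_R031	KP_F048	TACGGRAGGCAGCAG	KP_R031	TACHVGGGTATCTAAKCC	bacteria	FALSE	M	V3-V5	342	356	784	801	459	342	356	784	801
KP_F048-OP_R073	KP_F048	TACGGRAGGCAGCAG	OP_R073	CRTACTHCHCAGGYG	bacteria	FALSE	M	V3-V6	342	356	879	893	551	342	356	879	893
KP_F051-KP_R041	KP_F051	GTGCCAGCMGCNGCGG	KP_R041	CGTCAATTCMTTTGAGTT	bacteria	FALSE	M	V4-V6	514	529	907	924	410	514	529	907	924
KP_F051-OP_R030	KP_F051	GTGCCAGCMGCNGCGG	OP_R030	TCACRRCACGAGCTGWCGAC	bacteria	FALSE	M	V4-V7	514	529	1060	1079	565	514	529	1060	1079
OP_F116-KP_R060	OP_F116	YAACGAGCGCAACCC	KP_R060	GACGGGCGGTGWGTRCA	bacteria	FALSE	M	V7-V9	1099	1113	1390	1406	307	1099	1113	1390	1406
KP_F048-OP_R030	KP_F048	TACGGRAGGCAGCAG	OP_R030	TCACRRCACGAGCTGWCGAC	bacteria	FALSE	L	V3-V7	342	356	1060	1079	737	342	356	1060	1079
KP_F048-KP_R060	KP_F048	TACGGRAGGCAGCAG	KP_R060	GACGGGCGGTGWGTRCA	bacteria	FALSE	L	V3-V9	342	356	1390	1406	1064	342	356	1390	1406
KP_F056-KP_R077	KP_F056	AYTGGGYDTAAAGNG	KP_R077	GACGGGCGGTGTGTACAA	bacteria	FALSE	L	V4-V9	572	576	1389	1406	834	572	586	1389	1406
KP_F018-KP_R002	KP_F018	GYGCASCAGKCGMGAAW	KP_R002	TTACCGCGGCKGCTG	archaea	FALSE	S	-V4	U	U	518	532	NA	380	396	518	532
OP_F066-KP_R013	OP_F066	GGMTTAGATACCC	KP_R013	GGCCATGCACCWCCTCTC	archaea	FALSE	S	V5-V6	784	796	U	U	NA	784	796	1040	1057
KP_F018-KP_R032	KP_F018	GYGCASCAGKCGMGAAW	KP_R032	TACNVGGGTATCTAATCC	archaea	FALSE	M	V3-V5	U	U	784	801	NA	380	396	784	801
KP_F018-OP_R073	KP_F018	GYGCASCAGKCGMGAAW	OP_R073	CRTACTHCHCAGGYG	archaea	FALSE	M	V3-V5	U	U	879	893	NA	380	396	879	893
KP_F020-KP_R013	KP_F020	CAGCMGCCGCGGTAA	KP_R013	GGCCATGCACCWCCTCTC	archaea	FALSE	M	V3-V6	518	532	U	U	NA	518	532	1040	1057
KP_F022-KP_R063	KP_F022	AGGAATTGGCGGGGGAGCA	KP_R063	TACCTTGTTACGACTT	archaea	FALSE	M	V5-V9	U	U	1491	1506	NA	935	953	1491	1506
OP_F114-KP_R013	OP_F114	CCTAYGGGRBGCASCAG	KP_R013	GGCCATGCACCWCCTCTC	archaea	FALSE	L	V3-V6	340	356	U	U	NA	340	356	1040	1057
KP_F018-KP_R063	KP_F018	GYGCASCAGKCGMGAAW	KP_R063	TACCTTGTTACGACTT	archaea	FALSE	L	V3-V9	U	U	1491	1506	NA	380	396	1491	1506
OP_F066-OP_R016	OP_F066	GGMTTAGATACCC	OP_R016	CGGTGTGTGCAAGGAG	archaea	FALSE	L	V5-V9	784	796	U	U	NA	784	796	1410	1425
OP_F114-KP_R002	OP_F114	CCTAYGGGRBGCASCAG	KP_R002	TTACCGCGGCKGCTG	both	FALSE	S	V3-V4	340	356	518	532	192	340	356	518	532
KP_F020-KP_R032	KP_F020	CAGCMGCCGCGGTAA	KP_R032	TACNVGGGTATCTAATCC	both	FALSE	S	V4-V5	518	532	784	801	283	518	532	784	801
OP_F066-OP_R073	OP_F066	GGMTTAGATACCC	OP_R073	CRTACTHCHCAGGYG	both	FALSE	S	V5-V6	784	796	879	893	109	784	796	879	893
OP_F114-KP_R031	OP_F114	CCTAYGGGRBGCASCAG	KP_R031	TACHVGGGTATCTAAKCC	both	FALSE	M	V3-V5	340	356	784	801	461	340	356	784	801
OP_F114-OP_R073	OP_F114	CCTAYGGGRBGCASCAG	OP_R073	CRTACTHCHCAGGYG	both	FALSE	M	V3-V6	340	356	879	893	553	340	356	879	893
KP_F020-OP_R073	KP_F020	CAGCMGCCGCGGTAA	OP_R073	CRTACTHCHCAGGYG	both	FALSE	M	V4-V6	518	532	879	893	375	518	532	879	893
OP_F114-OP_R121	OP_F114	CCTAYGGGRBGCASCAG	OP_R121	ACGGGCGGTGWGTRC	both	FALSE	L	V3-V9	340	356	1391	1405	1065	340	356	1391	1405
KP_F020-OP_R121	KP_F020	CAGCMGCCGCGGTAA	OP_R121	ACGGGCGGTGWGTRC	both	FALSE	L	V4-V9	518	532	1391	1405	887	518	532	1391	1405
OP_F066-OP_R121	OP_F066	GGMTTAGATACCC	OP_R121	ACGGGCGGTGWGTRC	both	FALSE	L	V5-V9	784	796	1391	1405	621	784	796	1391	1405
KP_F078-OP_R010	KP_F078	GTGCCAGCMGCCGCGGTAA	OP_R010	GGACTACHVGGGTWTCTAAT	both	TRUE	S	V4-V5	514	532	786	805	291	514	532	786	805
KP_F031-KP_R021	KP_F031	AGAGTTTGATCCTGGCTCAG	KP_R021	TTACCGCGGCTGCTGGCAC	bacteria	TRUE	M	V1-V4	8	27	515	532	524	8	27	514	532
KP_F047-KP_R035	KP_F047	CCTACGGGNGGCWGCAG	KP_R035	GACTACHVGGGTATCTAATCC	bacteria	TRUE	M	V3-V5	340	356	784	804	464	340	356	784	804
OP_F009-OP_R029	OP_F009	GGATTAGATACCCBRGTAGTC	OP_R029	ACGTCRTCCCCDCCTTCCTC	bacteria	TRUE	M	V5-V8	784	868	1174	1193	409	784	804	1174	1193
KP_F014-KP_R011	KP_F014	TCCAGGCCCTACGGG	KP_R011	YCCGGCGTTGAMTCCAATT	archaea	TRUE	L	V3-V6	U	U	U	U	NA	333	347	955	973
KP_F034-KP_R065	KP_F034	AGAGTTTGATCMTGGCTCAG	KP_R065	TACGGYTACCTTGTTACGACTT	bacteria	TRUE	L	V1-V9	8	27	1491	1512	1504	8	27	1491	1512
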