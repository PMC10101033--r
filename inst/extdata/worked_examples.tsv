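example_id	kind	detected	ma	total	detected2	ma2	total2	f_first	r_last	n_single	expected
scnma_KP_F048-OP_R030_B	sc_nma	180	6	186	NA	NA	NA	NA	NA	NA	93.55
scnma_KP_F018-KP_R063_A	sc_nma	127	6	135	NA	NA	NA	NA	NA	NA	89.63
scnma_OP_F053-KP_R020_B	sc_nma	179	6	186	NA	NA	NA	NA	NA	NA	93.01
scnma_OP_F066-KP_R040_B	sc_nma	165	77	186	NA	NA	NA	NA	NA	NA	47.31
overall_OP_F114-OP_R121	sc_nma_overall	180	6	186	129	6	135	NA	NA	NA	92.52
overall_OP_F066-OP_R073	sc_nma_overall	182	85	186	126	49	135	NA	NA	NA	54.21
overall_KP_F078-OP_R010	sc_nma_overall	176	28	186	86	20	135	NA	NA	NA	66.67
overall_OP_F114-KP_R031	sc_nma_overall	180	9	186	134	20	135	NA	NA	NA	88.79
span_KP_F048-OP_R030	span	NA	NA	NA	NA	NA	NA	342	1079	NA	737
span_KP_F048-OP_R043	span	NA	NA	NA	NA	NA	NA	342	529	NA	187
multi_copy_bacteria	multi_copy_pct	NA	NA	186	NA	NA	NA	NA	NA	11	94.09
multi_copy_archaea	multi_copy_pct	NA	NA	135	NA	NA	NA	NA	NA	64	52.59
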