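M01_AKT_signaling	synthetic_catalogue	AKT1
M02_inflammasome	synthetic_catalogue	IL1B	NLRP3	TP53
M03_homocysteine_ox	synthetic_catalogue	MTHFR
M04_JNK_signaling	synthetic_catalogue	MAPK9
M05_lipoprotein_APOE	synthetic_catalogue	APOE	TOMM40
M06_tau_microtubule	synthetic_catalogue	MAPT
M07_synuclein_agg	synthetic_catalogue	SNCA
M08_kinase_GSK_CDK	synthetic_catalogue	CDK5	GSK3B
M09_endocytosis_immune	synthetic_catalogue	PICALM	CD33
M10_IL6_signaling	synthetic_catalogue	IL6
M11_apoptosis_cytc	synthetic_catalogue	CYCS	APOE
M12_synthetic_a	synthetic_catalogue	PLGENE17	PLGENE18
M13_synthetic_b	synthetic_catalogue	PLGENE19	PLGENE20	PLGENE21
M14_synthetic_c	synthetic_catalogue	PLGENE22	PLGENE23	PLGENE24
M15_synthetic_d	synthetic_catalogue	PLGENE25	PLGENE26	PLGENE27
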