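gene	chrom	start	end
AKT1	chr1	1000000	1020000
IL1B	chr2	1000000	1020000
NLRP3	chr3	1000000	1020000
TP53	chr4	1000000	1020000
MTHFR	chr5	1000000	1020000
MAPK9	chr6	1000000	1020000
APOE	chr7	1000000	1020000
TOMM40	chr8	1000000	1020000
MAPT	chr9	1000000	1020000
SNCA	chr10	1000000	1020000
CDK5	chr11	1000000	1020000
GSK3B	chr12	1000000	1020000
PICALM	chr13	1000000	1020000
CD33	chr14	1000000	1020000
IL6	chr15	1000000	1020000
CYCS	chr16	1000000	1020000
PLGENE17	chr17	1000000	1020000
PLGENE18	chr18	1000000	1020000
PLGENE19	chr19	1000000	1020000
PLGENE20	chr20	1000000	1020000
PLGENE21	chr21	1000000	1020000
PLGENE22	chr22	1000000	1020000
PLGENE23	chr1	6000000	6020000
PLGENE24	chr2	6000000	6020000
PLGENE25	chr3	6000000	6020000
PLGENE26	chr4	6000000	6020000
PLGENE27	chr5	6000000	6020000
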