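snp	chrom	pos
snp001	chr1	1000500
snp002	chr1	1003214
snp003	chr1	1005929
snp004	chr1	1008643
snp005	chr1	1011357
snp006	chr1	1014071
snp007	chr1	1016786
snp008	chr1	1019500
snp009	chr2	1000500
snp010	chr2	1005250
snp011	chr2	1010000
snp012	chr2	1014750
snp013	chr2	1019500
snp014	chr3	1000500
snp015	chr3	1004300
snp016	chr3	1008100
snp017	chr3	1011900
snp018	chr3	1015700
snp019	chr3	1019500
snp020	chr4	1000500
snp021	chr4	1003667
snp022	chr4	1006833
snp023	chr4	1010000
snp024	chr4	1013167
snp025	chr4	1016333
snp026	chr4	1019500
snp027	chr5	1000500
snp028	chr5	1004300
snp029	chr5	1008100
snp030	chr5	1011900
snp031	chr5	1015700
snp032	chr5	1019500
snp033	chr6	1000500
snp034	chr6	1004300
snp035	chr6	1008100
snp036	chr6	1011900
snp037	chr6	1015700
snp038	chr6	1019500
snp039	chr7	1000500
snp040	chr7	1002875
snp041	chr7	1005250
snp042	chr7	1007625
snp043	chr7	1010000
snp044	chr7	1012375
snp045	chr7	1014750
snp046	chr7	1017125
snp047	chr7	1019500
snp048	chr8	1000500
snp049	chr8	1004300
snp050	chr8	1008100
snp051	chr8	1011900
snp052	chr8	1015700
snp053	chr8	1019500
snp054	chr9	1000500
snp055	chr9	1003214
snp056	chr9	1005929
snp057	chr9	1008643
snp058	chr9	1011357
snp059	chr9	1014071
snp060	chr9	1016786
snp061	chr9	1019500
snp062	chr10	1000500
snp063	chr10	1003667
snp064	chr10	1006833
snp065	chr10	1010000
snp066	chr10	1013167
snp067	chr10	1016333
snp068	chr10	1019500
snp069	chr11	1000500
snp070	chr11	1005250
snp071	chr11	1010000
snp072	chr11	1014750
snp073	chr11	1019500
snp074	chr12	1000500
snp075	chr12	1004300
snp076	chr12	1008100
snp077	chr12	1011900
snp078	chr12	1015700
snp079	chr12	1019500
snp080	chr13	1000500
snp081	chr13	1005250
snp082	chr13	1010000
snp083	chr13	1014750
snp084	chr13	1019500
snp085	chr14	1000500
snp086	chr14	1006833
snp087	chr14	1013167
snp088	chr14	1019500
snp089	chr15	1000500
snp090	chr15	1005250
snp091	chr15	1010000
snp092	chr15	1014750
snp093	chr15	1019500
snp094	chr16	1000500
snp095	chr16	1006833
snp096	chr16	1013167
snp097	chr16	1019500
snp098	chr17	1000500
snp099	chr17	1005250
snp100	chr17	1010000
snp101	chr17	1014750
snp102	chr17	1019500
snp103	chr18	1000500
snp104	chr18	1005250
snp105	chr18	1010000
snp106	chr18	1014750
snp107	chr18	1019500
snp108	chr19	1000500
snp109	chr19	1005250
snp110	chr19	1010000
snp111	chr19	1014750
snp112	chr19	1019500
snp113	chr20	1000500
snp114	chr20	1005250
snp115	chr20	1010000
snp116	chr20	1014750
snp117	chr20	1019500
snp118	chr21	1000500
snp119	chr21	1005250
snp120	chr21	1010000
snp121	chr21	1014750
snp122	chr21	1019500
snp123	chr22	1000500
snp124	chr22	1005250
snp125	chr22	1010000
snp126	chr22	1014750
snp127	chr22	1019500
snp128	chr1	6000500
snp129	chr1	6005250
snp130	chr1	6010000
snp131	chr1	6014750
snp132	chr1	6019500
snp133	chr2	6000500
snp134	chr2	6006833
snp135	chr2	6013167
snp136	chr2	6019500
snp137	chr3	6000500
snp138	chr3	6006833
snp139	chr3	6013167
snp140	chr3	6019500
snp141	chr4	6000500
snp142	chr4	6006833
snp143	chr4	6013167
snp144	chr4	6019500
snp145	chr5	6000500
snp146	chr5	6006833
snp147	chr5	6013167
snp148	chr5	6019500
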