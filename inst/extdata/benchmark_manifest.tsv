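pdb_code	length	catalytic_residues	ec	detail	pid_nearest_template
1ogx	131	16,40,103	5.3.3.1	Ketosteroid isomerase	32.8
1oh0	131	16,40,103	5.3.3.1	Ketosteroid isomerase	33.6
1w6y	131	16,40,103	5.3.3.1	Ketosteroid isomerase	33.6
1p6o	161	62,64,91,94	3.5.4.1	Cytosine deaminase	27.7
4fua	215	73,92,94,155	4.1.2.17	L-fuculose-1-phosphonate aldolase	40.9
2nlr	234	104,120	3.2.1.4	Endoglucanase	70.7
1tqh	247	25,94,193,223	3.1.1.1	Carboxylesterase	31.6
1ney	247	12,95,165	5.3.1.1	Triosephosphate isomerase	53.4
1xpz	258	94,96,119,199	4.2.1.1	Human carbonic anhydrase	79.8
1jcl	260	47,102,137,167,201	4.1.2.4	Deoxyribose-phosphate aldolase	32.3
3ia2	271	28,94,95,222,251	3.1.1.2	Esterase	53.9
2gke	274	73,208,217	5.1.1.7	Diaminopimelate epimerase	77.4
1eh5	279	41,115,233,289	3.1.2.22	Palmitoyl-protein thioesterase 1	24.7
2jaj	289	78,172,268,273	3.5.3.18	Dimethylarginine dimethylaminohydrolase 1	29.9
1h2j	303	139,202,228	3.2.1.4	Endoglucanase	68.0
6cpa	307	69,72,145,196,248,270	3.4.17.1	Carboxypeptidase A	79.5
1hqd	320	17,87,88,264,286	3.1.1.3	Lipase	77.3
3veu	386	32,219	3.4.23.46	Human beta secretase	53.3
2jie	454	167,298,356	3.2.1.21	beta-glucosidase B	46.4
1oif	468	166,295,351	3.2.1.21	Family 1 beta-glucosidase	68.3
1oim	468	166,295,351	3.2.1.21	Family 1 beta-glucosidase	68.3
1ju3	583	44,117,118,259,287	3.1.1.84	Cocaine esterase	29.3
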