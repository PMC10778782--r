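gene_id	S1	S2	S3	S4	S5	S6
g1	2.4697	2.9029	7.6999	6.6859	20.9474	21.4351
g2	27.0838	8.5471	3.1467	27.0872	8.7689	3.0799
g3	2.0138	6.3092	17.5496	14.9373	6.141	2.4198
g4	3.6659	8.7689	22.7576	26.8776	9.017	3.0327
g5	2.8577	3.4903	3.0042	3.3201	3.6693	3.1582
g6	2.9781	7.3825	18.3466	21.6771	7.592	2.4625
g7	2.045	5.9701	18.095	15.3887	5.8101	2.4596
g8	2.117	2.4596	2.2255	2.0138	2.3396	1.9155
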