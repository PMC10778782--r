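gene_id	NF_1	NF_2	NF_3	LS_1	LS_2	LS_3
g1	164	180	148	41	45	37
g2	132	145	119	76	83	68
g3	95	104	85	47	52	43
g4	76	83	68	132	145	119
g5	41	45	37	164	180	148
g6	82	90	74	82	90	74
g7	47	52	43	95	104	85
g8	55	61	50	55	61	50
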