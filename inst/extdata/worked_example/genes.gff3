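##gff-version 3
chr1	sim	gene	20000	21200	.	+	.	ID=g1
chr1	sim	CDS	20100	20399	.	+	0	ID=g1.cds1;Parent=g1
chr1	sim	CDS	20600	21001	.	+	0	ID=g1.cds2;Parent=g1
chr1	sim	gene	40000	41200	.	+	.	ID=g2
chr1	sim	CDS	40100	40399	.	+	0	ID=g2.cds1;Parent=g2
chr1	sim	CDS	40600	41001	.	+	0	ID=g2.cds2;Parent=g2
chr1	sim	gene	60000	61200	.	-	.	ID=g3
chr1	sim	CDS	60100	60399	.	-	0	ID=g3.cds1;Parent=g3
chr1	sim	CDS	60600	61001	.	-	0	ID=g3.cds2;Parent=g3
chr1	sim	gene	80000	81200	.	+	.	ID=g4
chr1	sim	CDS	80100	80399	.	+	0	ID=g4.cds1;Parent=g4
chr1	sim	CDS	80600	81001	.	+	0	ID=g4.cds2;Parent=g4
chr2	sim	gene	5000	6200	.	+	.	ID=g5
chr2	sim	CDS	5100	5399	.	+	0	ID=g5.cds1;Parent=g5
chr2	sim	CDS	5600	6001	.	+	0	ID=g5.cds2;Parent=g5
chr2	sim	gene	20000	21200	.	+	.	ID=g6
chr2	sim	CDS	20100	20399	.	+	0	ID=g6.cds1;Parent=g6
chr2	sim	CDS	20600	21001	.	+	0	ID=g6.cds2;Parent=g6
chr2	sim	gene	40000	41200	.	-	.	ID=g7
chr2	sim	CDS	40100	40399	.	-	0	ID=g7.cds1;Parent=g7
chr2	sim	CDS	40600	41001	.	-	0	ID=g7.cds2;Parent=g7
chr2	sim	gene	90000	91200	.	+	.	ID=g8
chr2	sim	CDS	90100	90399	.	+	0	ID=g8.cds1;Parent=g8
chr2	sim	CDS	90600	91001	.	+	0	ID=g8.cds2;Parent=g8
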