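##fileformat=VCFv4.2
##contig=<ID=chr1,length=100000>
##contig=<ID=chr2,length=100000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5	S6
chr1	1000	bg1_01	A	G	     99	.	.	GT	0/0	0/1	0/0	0/1	0/0	0/1
chr1	5000	bg1_02	A	G	     99	.	.	GT	0/1	0/0	0/1	0/0	0/1	0/0
chr1	10000	bg1_03	A	G	     99	.	.	GT	0/1	0/1	0/0	0/0	0/1	0/1
chr1	15000	bg1_04	A	G	     99	.	.	GT	1/1	0/1	0/0	0/1	1/1	0/0
chr1	18646	cis_1	A	G	    250	.	.	GT	0/0	0/0	0/1	0/1	1/1	1/1
chr1	19200	cis_2	A	G	    250	.	.	GT	0/0	0/0	0/1	0/1	1/1	1/1
chr1	19700	cis_3	A	G	    250	.	.	GT	0/0	0/0	0/1	0/1	1/1	1/1
chr1	25000	bg1_05	A	G	     99	.	.	GT	0/0	0/0	0/1	0/1	0/0	0/0
chr1	30000	bg1_06	A	G	     99	.	.	GT	0/1	1/1	0/1	0/0	0/1	1/1
chr1	35000	bg1_07	A	G	     99	.	.	GT	0/0	1/1	0/0	1/1	0/0	1/1
chr1	45000	bg1_08	A	G	     99	.	.	GT	0/0	0/1	0/0	0/1	0/0	0/1
chr1	55000	bg1_09	A	G	     99	.	.	GT	0/1	0/0	0/1	0/0	0/1	0/0
chr1	65000	bg1_10	A	G	     99	.	.	GT	0/1	0/1	0/0	0/0	0/1	0/1
chr1	75000	bg1_11	A	G	     99	.	.	GT	1/1	0/1	0/0	0/1	1/1	0/0
chr1	85000	bg1_12	A	G	     99	.	.	GT	0/0	0/0	0/1	0/1	0/0	0/0
chr1	95000	bg1_13	A	G	     30	.	.	GT	0/1	1/1	0/1	0/0	0/1	1/1
chr2	2000	bg2_01	A	G	     99	.	.	GT	1/1	0/1	0/0	0/1	1/1	0/0
chr2	10000	bg2_02	A	G	     99	.	.	GT	0/0	0/0	0/1	0/1	0/0	0/0
chr2	15000	bg2_03	A	G	     99	.	.	GT	0/1	1/1	0/1	0/0	0/1	1/1
chr2	30000	bg2_04	A	G	     99	.	.	GT	0/0	1/1	0/0	1/1	0/0	1/1
chr2	35000	bg2_05	A	G	     99	.	.	GT	0/0	0/1	0/0	0/1	0/0	0/1
chr2	50000	hot_1	A	G	    250	.	.	GT	0/0	0/1	1/1	1/1	0/1	0/0
chr2	50400	hot_2	A	G	    250	.	.	GT	0/0	0/1	1/1	1/1	0/1	0/0
chr2	50800	hot_3	A	G	    250	.	.	GT	0/0	0/1	1/1	1/1	0/1	0/0
chr2	60000	bg2_06	A	G	     99	.	.	GT	0/1	0/0	0/1	0/0	0/1	0/0
chr2	70000	trans_1	A	G	    250	.	.	GT	1/1	0/1	0/0	1/1	0/1	0/0
chr2	70500	trans_2	A	G	    250	.	.	GT	1/1	0/1	0/0	1/1	0/1	0/0
chr2	71000	trans_3	A	G	    250	.	.	GT	1/1	0/1	0/0	1/1	0/1	0/0
chr2	80000	bg2_07	A	G	     99	.	.	GT	0/1	0/1	0/0	0/0	0/1	0/1
chr2	95000	bg2_08	A	G	     99	.	.	GT	0/0	0/0	0/0	0/0	0/0	0/0
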