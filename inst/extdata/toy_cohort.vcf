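##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=CADD,Number=1,Type=Float,Description="CADD PHRED deleteriousness score">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1	P2	M1	M2	I1	C1
1	1000	.	A	G	.	.	GENE=GENE1;CSQ_CLASS=synonymous;CADD=30	GT	0/1	0/0	0/0	0/0	0/0	0/0
1	2000	.	C	T	.	.	GENE=GENE1;CSQ_CLASS=synonymous;CADD=10	GT	0/0	0/1	0/0	0/0	0/0	0/0
2	1500	.	G	A	.	.	GENE=GENE2;CSQ_CLASS=synonymous	GT	1/1	0/0	0/0	0/0	0/0	0/0
2	2500	.	T	C	.	.	GENE=GENE2;CSQ_CLASS=missense;CADD=10	GT	0/1	0/0	0/0	0/0	0/0	0/0
3	1200	.	A	T	.	.	GENE=GENE3;CSQ_CLASS=missense;CADD=25	GT	0/0	1/1	0/0	0/0	0/0	0/0
3	2200	.	G	C	.	.	GENE=GENE3;CSQ_CLASS=splice_altering	GT	0/1	0/0	0/0	0/0	0/0	0/0
4	500	.	C	G	.	.	GENE=GENE4;CSQ_CLASS=missense;CADD=28	GT	0|1	0/0	0/0	0/0	0/0	0/0
4	843508	rs1134921	C	T	.	.	GENE=GAK;CSQ_CLASS=missense;CADD=26	GT	0/0	1/1	0/0	0/0	0/0	0/0
5	700	.	G	T	.	.	GENE=GENE5;CSQ_CLASS=stop_gain;CADD=35	GT	0/0	0/1	0/0	0/0	0/0	0/0
6	900	.	A	C	.	.	GENE=GENE6;CSQ_CLASS=missense;CADD=30	GT	1/1	0/0	0/0	0/0	0/0	0/0
7	1100	.	C	A	.	.	GENE=GENE7;CSQ_CLASS=missense;CADD=27	GT	0/1	0/0	0/1	0/0	0/0	0/0
7	1300	.	G	A	.	.	GENE=GENE7;CSQ_CLASS=missense;CADD=29	GT	0/1	0/0	0/0	0/0	0/1	0/0
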