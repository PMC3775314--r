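##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	M001	M002	F001	F002
X	10001	snp_a	A	G	.	PASS	.	GT	0	1	0/1	1/1
X	11001	snp_b	C	T	.	PASS	.	GT	1	0	0/0	0/1
X	12001	snp_c	G	A	.	PASS	.	GT	0	0	1|1	0|1
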