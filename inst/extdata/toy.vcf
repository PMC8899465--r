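##fileformat=VCFv4.2
##contig=<ID=1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3
1	120	snpA	A	G	.	PASS	.	GT	0/0	0/1	1/1
1	250	snpM	C	G,T	.	PASS	.	GT	0/1	0/0	0/2
1	410	snpB	T	C	.	PASS	.	GT	0|1	1|1	0|0
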