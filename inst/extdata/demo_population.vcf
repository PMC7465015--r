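##fileformat=VCFv4.2
##contig=<ID=chrA,length=200000>
##contig=<ID=chrB,length=200000>
##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrA	52850	.	A	G	50	PASS	AF=0.12
chrA	53400	.	C	T	50	PASS	AF=0.31
chrA	54100	.	G	A,C	50	PASS	AF=0.05,0.02
chrB	12345	.	T	C	50	PASS	AF=0.40
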