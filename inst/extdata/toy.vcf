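##fileformat=VCFv4.2
##INFO=<ID=INFO,Number=1,Type=Float,Description="Imputation info score">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">
##contig=<ID=1>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
1	10000	rs1	G	A	.	PASS	INFO=0.95	GT:DS	0/0:0.1	0/1:1.0	1/1:1.9	0/1:0.8
1	20000	rs2	C	T	.	PASS	INFO=0.80	GT:DS	0/1:1.2	0/0:0.0	0/1:1.1	1/1:2.0
1	30000	rs3	A	C	.	PASS	INFO=0.99	GT:DS	0/0:0.0	0/0:0.2	0/1:0.9	0/0:0.1
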