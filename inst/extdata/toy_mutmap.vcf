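##fileformat=VCFv4.2
##source=hand-built 10-record filter fixture (one-bulk design: PARENT + BULK1)
##contig=<ID=chr1,length=10000000>
##INFO=<ID=MQ,Number=1,Type=Integer,Description="RMS mapping quality">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Allelic depths, forward strand">
##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Allelic depths, reverse strand">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	PARENT	BULK1
chr1	1000	.	A	G	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	0/1:10,10:5,5:5,5
chr1	2000	.	C	T	60	.	MQ=60	GT:AD:ADF:ADR	./.:0,0:0,0:0,0	0/1:10,10:5,5:5,5
chr1	3000	.	G	A	60	.	MQ=60	GT:AD:ADF:ADR	0/1:10,10:5,5:5,5	0/1:10,10:5,5:5,5
chr1	4000	.	A	G,T	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0,0:10,0,0:10,0,0	1/2:5,10,5:3,5,2:2,5,3
chr1	5000	.	A	AT	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	0/1:10,10:5,5:5,5
chr1	6000	.	T	C	60	.	MQ=20	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	0/1:10,10:5,5:5,5
chr1	7000	.	G	T	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	0/1:20,20:20,0:0,20
chr1	8000	.	C	A	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	0/1:2,2:1,1:1,1
chr1	9000	.	A	C	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	1/1:0,300:0,150:0,150
chr1	10000	.	T	G	60	.	MQ=60	GT:AD:ADF:ADR	0/0:20,0:10,0:10,0	1/1:0,18:0,9:0,9
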