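##fileformat=VCFv4.2
##INFO=<ID=QD,Number=1,Type=Float,Description="Variant Confidence/Quality by Depth">
##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric Odds Ratio">
##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher Strand">
##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS Mapping Quality">
##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping Quality Rank Sum">
##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read Pos Rank Sum">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5	s6
chr16	1455	.	G	A	80	PASS	QD=12.1;SOR=1.2;FS=4.0;MQ=58.9;MQRankSum=0.4;ReadPosRankSum=1.1	GT:AD	0/1:12,11	0/0:20,0	1/1:0,19	0/1:9,8	0/0:15,0	0/1:10,12
chr16	2001	.	C	T	45	PASS	QD=1.4;SOR=0.9;FS=2.2;MQ=59.1;MQRankSum=0.1;ReadPosRankSum=0.3	GT:AD	0/0:18,0	0/1:8,9	0/0:14,0	./.:0,0	0/1:7,7	0/0:13,0
chr16	3200	.	T	C	95	PASS	QD=15.3;SOR=3.6;FS=1.1;MQ=60.0;MQRankSum=-0.2;ReadPosRankSum=0.8	GT:AD	1/1:0,22	0/1:11,13	0/1:10,10	0/0:17,0	1/1:0,16	0/1:12,14
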