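##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##contig=<ID=chr1,length=248956422>
##contig=<ID=chr2,length=242193529>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TUMOR
chr1	10100	.	A	G	50	PASS	.	GT:AD:DP	0/1:45,5:50
chr1	20200	.	C	T	60	PASS	.	GT:AD:DP	0/1:27,3:30
chr1	30300	.	G	A,C	40	PASS	.	GT:AD:DP	0/1/2:30,6,4:40
chr2	40400	.	T	C	70	PASS	.	GT:AD:DP	0/1:80,20:100
chr2	50500	.	G	T	30	PASS	.	GT:AD:DP	./.:.:.
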