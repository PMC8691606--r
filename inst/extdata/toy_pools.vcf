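##fileformat=VCFv4.2
##source=starchbsa-toy
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1	P2	HP	LP
chr01	1200	.	A	G	.	PASS	.	AD	0,12	10,0	3,9	8,2
chr01	5400	.	C	T,G	.	PASS	.	AD	2,5,5	9,0,0	4,4,4	5,3,3
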