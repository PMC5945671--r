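##fileformat=VCFv4.2
##source=synthetic example, not derived from any patient data
##INFO=<ID=DP4,Number=4,Type=Integer,Description="Strand read counts: ref-fwd,ref-rev,alt-fwd,alt-rev">
##INFO=<ID=CTX,Number=1,Type=String,Description="Reference trinucleotide context">
##INFO=<ID=FUNC,Number=1,Type=String,Description="Functional annotation class">
##contig=<ID=chr1>
##contig=<ID=chr2>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	1000	.	C	A	60	PASS	DP4=20,18,5,6;CTX=ACA;FUNC=nonsynonymous
chr1	2000	.	G	T	60	PASS	DP4=15,15,4,3;CTX=TGT;FUNC=synonymous
chr2	500	.	T	A,G	60	PASS	DP4=10,10,3,4;CTX=ATG;FUNC=stopgain
chr2	900	.	AT	A	60	PASS	CTX=.;FUNC=other
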