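sample_id	gene	mclass	chrom	pos	ref	alt	vaf
S1	TP53	nonsynonymous_snv	17	7578406	C	T	0.45
S1	DNMT3A	synonymous	2	25468121	G	A	0.12
S2	TP53	indel	17	7577550	AG	A	NA
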