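haplotype	accession	p36	p47	p63	p77	p103	p106	p142	p155	p171	p173	p198	p217	p218	p283
S-A	MN256463	T	G	T	T	T	TT	T	G	G	T	C	T	T	T
S-B	MN256465	T	G	T	C	C	-	T	G	G	T	C	C	-	T
s-a	MN256464	T	G	T	T	T	TT	C	A	A	C	T	T	T	C
s-b	MN256465	A	T	G	C	C	TT	T	G	G	T	C	T	T	T
s-c	MN256466	T	G	G	C	C	TT	T	G	G	T	C	T	T	T
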