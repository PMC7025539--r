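group	haplotype_combination	genotype_63	genotype_283	homozygous_or_null
G1	S-B/-	TT	TT	yes
G1	S-A/-	TT	TT	yes
G1	S-A/s-a	TT	TC	no
G1	S-A/s-b	TG	TT	no
G1	S-A/s-c	TG	TT	no
G2	s-a/s-a	TT	CC	no
G2	s-a/s-b	TG	CT	no
G2	s-a/s-c	TG	CT	no
G2	s-b/s-b	GG	TT	no
G2	s-b/s-c	GG	TT	no
G2	s-c/s-c	GG	TT	no
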