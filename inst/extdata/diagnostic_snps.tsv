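locus	region	position	base_A	race_A	base_B	race_B	informative_for	note
LRR	Cr	49	A	pet	G	fav	L14,L15
LRR	Cr	154	A	pet	T	fav	L14,L15
LRR	Cr	195	C	pet	A	fav	L14,L15
LRR	Cr	267	A	pet	T	fav	L14,L15
LRR	Cr	330	A	pet	T	fav	L14,L15
LRR	Cr	493	C	pet	A	fav	L14,L15
LRR	Cr	552	T	pet	C	fav	L14,L15
LRR	Cr	572	C	pet	G	fav	L14,L15
LRR	Cr	581	A	pet	C	fav	L14,L15
ReqQ	Cr	55	T	pet	C	fav	L14,L15
ReqQ	Cr	302	T	pet	C	fav	L14,L15
ReqQ	Cr	352	G	pet	A	fav	L14,L15
ReqQ	Cr	362	A	pet	G	fav	L14,L15
ReqQ	Cr	365	A	pet	T	fav	L14,L15
ReqQ	Cr	366	A	pet	C	fav	L14,L15
ReqQ	Cr	376	C	pet	T	fav	L14,L15
ReqQ	Cr	391	G	pet	A	fav	L14,L15
ReqQ	Cr	464	A	pet	T	fav	L14,L15
ReqQ	Cr	469	C	pet	T	fav	L14,L15
Mat	Sd	85	G	pet	A	fav	L15
Mat	Sd	301	C	pet	T	fav	L15	polymorphic_in_parents: maternal fav base reads C; hybrids can score homozygous here
Mat	Sd	327	C	pet	T	fav	L15	polymorphic_in_parents: maternal fav base reads C; hybrids can score homozygous here
Mat	Sd	358	T	pet	A	fav	L15
Mat	Sd	430	T	pet	C	fav	L15	AseI recognition site overlaps this SNP in the in-silico assay
Mat	Sd	281	A	pet	C	fav	L14	polymorphic_in_parents: maternal pet base reads C; hybrids can score homozygous here
B9	Yb	258	R	mel	T	ros	L13	paternal site printed as ambiguity R; maternal T outside the R expansion is left as printed, not reconciled
Parn	Yb	186	Y	mel	C	ros	L13	paternal heterozygous site; not a race-diagnostic base pair
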