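name	39	114	122	130	145	146	200	269	334	466	475	559	649
A	T	A	A	A	G	A	T	G	A	A	T	G	T
B	-	G	G	G	A	T	C	G	G	A	T	A	A
C	-	A	G	G	A	T	C	A	A	C	-	G	T
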