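horse	c_pos	ref	transcript	cyp2d50_1	cyp2d50_2	ncbi
1	111	C	C/A	HET (C/A)	HOM (C/C)	HET (C/A)
1	582	C	C/T	HET (C/T)	HOM (C/C)	HET (C/T)
1	867	G	G/T	HET (G/T)	HOM (A/A)	HET (G/T)
1	1185	C	C/G	HET (C/G)	HOM (G/G)	HOM (G/G)
1	1198	C	C/A	HET (C/A)	HOM (A/A)	HOM (A/A)
1	1471	T	G/G	MUT (G/G)	HOM (G/G)	HOM (G/G)
2	517	C	A/C	HET (A/C)	HOM (C/C)	HET (A/C)
2	522	C	C/G	HET (C/G)	HOM (G/G)	HET (C/G)
2	582	C	C/T	HET (C/T)	HOM (C/C)	HET (C/T)
2	867	G	G/T	HET (G/T)	HOM (A/A)	HET (G/T)
2	1471	T	T/G	HET (T/G)	MUT (T/T)	MUT (T/T)
3	111	C	C/A	HET (C/A)	HOM (C/C)	HET (C/A)
3	582	C	T/T	MUT (T/T)	HOM (C/C)	MUT (T/T)
3	867	G	T/T	MUT (T/T)	HOM (A/A)	MUT (T/T)
3	1290	C	C/T	HET (C/T)	MUT (T/T)	MUT (T/T)
3	1471	T	G/G	MUT (G/G)	HOM (G/G)	HOM (G/G)
4	111	C	C/A	HET (C/A)	HOM (C/C)	HET (C/A)
4	582	C	C/T	HET (C/T)	HOM (C/C)	HET (C/T)
4	867	G	G/T	HET (G/T)	HOM (A/A)	HET (G/T)
4	1185	C	C/G	HET (C/G)	HOM (G/G)	HOM (G/G)
4	1198	C	C/A	HET (C/A)	HOM (A/A)	HOM (A/A)
4	1471	T	G/G	MUT (G/G)	HET (G/T)	HET (G/T)
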