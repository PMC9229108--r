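element	aromatic	h	nsingle	ndouble	ntriple	naromatic	tpsa
N	0	2	1	0	0	0	26.02
N	0	1	2	0	0	0	12.03
N	0	0	3	0	0	0	3.24
N	0	1	0	1	0	0	23.85
N	0	0	1	1	0	0	12.36
N	0	0	0	0	1	0	23.79
N	0	0	1	2	0	0	11.68
N	0	0	0	1	1	0	13.60
N	1	0	0	0	0	2	12.89
N	1	0	0	0	0	3	4.41
N	1	0	1	0	0	2	4.93
N	1	0	0	1	0	2	8.39
N	1	1	0	0	0	2	15.79
O	0	1	1	0	0	0	20.23
O	0	0	2	0	0	0	9.23
O	0	0	0	1	0	0	17.07
O	1	0	0	0	0	2	13.14
S	0	1	1	0	0	0	38.80
S	0	0	2	0	0	0	25.30
S	0	0	0	1	0	0	32.09
S	0	0	2	1	0	0	19.21
S	0	0	2	2	0	0	8.38
S	1	0	0	0	0	2	28.24
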