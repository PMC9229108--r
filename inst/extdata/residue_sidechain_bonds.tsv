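residue	from	to	order
A	CA	CB	1
R	CA	CB	1
R	CB	CG	1
R	CG	CD	1
R	CD	NE	1
R	NE	CZ	1
R	CZ	NH1	2
R	CZ	NH2	1
N	CA	CB	1
N	CB	CG	1
N	CG	OD1	2
N	CG	ND2	1
D	CA	CB	1
D	CB	CG	1
D	CG	OD1	2
D	CG	OD2	1
C	CA	CB	1
C	CB	SG	1
E	CA	CB	1
E	CB	CG	1
E	CG	CD	1
E	CD	OE1	2
E	CD	OE2	1
Q	CA	CB	1
Q	CB	CG	1
Q	CG	CD	1
Q	CD	OE1	2
Q	CD	NE2	1
H	CA	CB	1
H	CB	CG	1
H	CG	ND1	ar
H	ND1	CE1	ar
H	CE1	NE2	ar
H	NE2	CD2	ar
H	CD2	CG	ar
I	CA	CB	1
I	CB	CG1	1
I	CB	CG2	1
I	CG1	CD1	1
L	CA	CB	1
L	CB	CG	1
L	CG	CD1	1
L	CG	CD2	1
K	CA	CB	1
K	CB	CG	1
K	CG	CD	1
K	CD	CE	1
K	CE	NZ	1
M	CA	CB	1
M	CB	CG	1
M	CG	SD	1
M	SD	CE	1
F	CA	CB	1
F	CB	CG	1
F	CG	CD1	ar
F	CD1	CE1	ar
F	CE1	CZ	ar
F	CZ	CE2	ar
F	CE2	CD2	ar
F	CD2	CG	ar
P	CA	CB	1
P	CB	CG	1
P	CG	CD	1
P	CD	N	1
S	CA	CB	1
S	CB	OG	1
T	CA	CB	1
T	CB	OG1	1
T	CB	CG2	1
W	CA	CB	1
W	CB	CG	1
W	CG	CD1	ar
W	CD1	NE1	ar
W	NE1	CE2	ar
W	CE2	CD2	ar
W	CD2	CG	ar
W	CD2	CE3	ar
W	CE3	CZ3	ar
W	CZ3	CH2	ar
W	CH2	CZ2	ar
W	CZ2	CE2	ar
V	CA	CB	1
V	CB	CG1	1
V	CB	CG2	1
Y	CA	CB	1
Y	CB	CG	1
Y	CG	CD1	ar
Y	CD1	CE1	ar
Y	CE1	CZ	ar
Y	CZ	CE2	ar
Y	CE2	CD2	ar
Y	CD2	CG	ar
Y	CZ	OH	1
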