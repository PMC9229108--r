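residue	atom	element	aromatic	h
A	CB	C	0	3
R	CB	C	0	2
R	CG	C	0	2
R	CD	C	0	2
R	NE	N	0	1
R	CZ	C	0	0
R	NH1	N	0	1
R	NH2	N	0	2
N	CB	C	0	2
N	CG	C	0	0
N	OD1	O	0	0
N	ND2	N	0	2
D	CB	C	0	2
D	CG	C	0	0
D	OD1	O	0	0
D	OD2	O	0	1
C	CB	C	0	2
C	SG	S	0	1
E	CB	C	0	2
E	CG	C	0	2
E	CD	C	0	0
E	OE1	O	0	0
E	OE2	O	0	1
Q	CB	C	0	2
Q	CG	C	0	2
Q	CD	C	0	0
Q	OE1	O	0	0
Q	NE2	N	0	2
H	CB	C	0	2
H	CG	C	1	0
H	ND1	N	1	1
H	CE1	C	1	1
H	NE2	N	1	0
H	CD2	C	1	1
I	CB	C	0	1
I	CG1	C	0	2
I	CG2	C	0	3
I	CD1	C	0	3
L	CB	C	0	2
L	CG	C	0	1
L	CD1	C	0	3
L	CD2	C	0	3
K	CB	C	0	2
K	CG	C	0	2
K	CD	C	0	2
K	CE	C	0	2
K	NZ	N	0	2
M	CB	C	0	2
M	CG	C	0	2
M	SD	S	0	0
M	CE	C	0	3
F	CB	C	0	2
F	CG	C	1	0
F	CD1	C	1	1
F	CD2	C	1	1
F	CE1	C	1	1
F	CE2	C	1	1
F	CZ	C	1	1
P	CB	C	0	2
P	CG	C	0	2
P	CD	C	0	2
S	CB	C	0	2
S	OG	O	0	1
T	CB	C	0	1
T	OG1	O	0	1
T	CG2	C	0	3
W	CB	C	0	2
W	CG	C	1	0
W	CD1	C	1	1
W	NE1	N	1	1
W	CE2	C	1	0
W	CD2	C	1	0
W	CE3	C	1	1
W	CZ3	C	1	1
W	CH2	C	1	1
W	CZ2	C	1	1
V	CB	C	0	1
V	CG1	C	0	3
V	CG2	C	0	3
Y	CB	C	0	2
Y	CG	C	1	0
Y	CD1	C	1	1
Y	CD2	C	1	1
Y	CE1	C	1	1
Y	CE2	C	1	1
Y	CZ	C	1	0
Y	OH	O	0	1
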