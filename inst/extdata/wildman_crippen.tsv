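type	logp	description
C1	0.1441	primary or secondary aliphatic carbon, C/H neighbors only
C2	0.0	tertiary or quaternary aliphatic carbon, C/H neighbors only
C3	-0.2035	primary or secondary aliphatic carbon with heteroatom neighbor
C4	-0.2051	tertiary or quaternary aliphatic carbon with heteroatom neighbor
C5	-0.2783	carbon double-bonded to a heteroatom (carbonyl, guanidine)
C6	0.1551	sp2 carbon in C=C
C7	0.0017	sp carbon
C8	0.08452	CH3 attached to aromatic carbon
C9	-0.1444	CH3 attached to aromatic heteroatom
C10	-0.0516	CH2 attached to aromatic atom
C11	0.1193	CH attached to aromatic atom
C12	-0.0967	quaternary C attached to aromatic atom
C18	0.1581	aromatic CH
C19	0.2955	aromatic bridgehead carbon (three aromatic neighbors)
C20	0.2713	aromatic carbon single-bonded to aromatic atom
C21	0.136	aromatic carbon single-bonded to aliphatic carbon
C22	0.4619	aromatic carbon single-bonded to nitrogen
C23	0.5437	aromatic carbon single-bonded to oxygen
C24	0.1893	aromatic carbon single-bonded to sulfur
C25	-0.8186	aromatic carbon double-bonded to C/N/O
C26	0.264	sp2 carbon bridging aromatic system
C27	0.2148	sp3 carbon attached to other element
CS	0.08129	carbon fallback
H1	0.123	hydrogen on carbon
H2	-0.2677	hydrogen on alcohol/phenol oxygen or on sulfur
H3	0.2142	hydrogen on nitrogen (amine, amide)
H4	0.298	hydrogen on acid oxygen (O-H of O=C-OH)
HS	0.1125	hydrogen fallback
N1	-1.019	primary aliphatic amine NH2
N2	-0.7096	secondary aliphatic NH (amine or amide)
N3	-1.027	primary aromatic amine NH2
N4	-0.5188	secondary NH attached to aromatic atom
N5	0.08387	imine =NH
N6	0.1836	substituted imine =N-
N7	-0.3187	tertiary aliphatic N
N8	-0.4458	tertiary N attached to aromatic atom
N9	0.01508	nitrile N
N11	-0.3239	aromatic neutral nitrogen
NS	-0.4806	nitrogen fallback
O1	0.1552	aromatic oxygen
O2	-0.2893	alcohol/phenol/acid hydroxyl oxygen
O3	-0.0684	aliphatic ether oxygen
O4	-0.4195	aromatic-attached ether oxygen
O9	-0.1526	aliphatic carbonyl oxygen (amide, acid, ketone, aldehyde)
O10	0.1129	aromatic-conjugated carbonyl oxygen
O11	0.4833	carbonyl oxygen with two hetero substituents
OS	-0.1188	oxygen fallback
S1	0.6482	neutral aliphatic sulfur (thiol, thioether, disulfide)
S3	0.6237	aromatic sulfur
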