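term	coefficient	exponent	description
intercept	-1.041	1	regression intercept
CX	1.244	0.6	weighted count of carbon and halogen atoms
NO	-1.017	0.9	count of nitrogen and oxygen atoms
PRX	0.406	1	proximity effect of N/O pairs (bonded 2, one atom apart 1, amide 2)
UB	-0.145	0.8	count of unsaturated (double/triple, Kekule aromatic) bonds
HB	0.511	1	dummy: intramolecular hydrogen bond
POL	0.268	1	count of aromatic polar substituents
AMP	-2.215	1	amphoteric property (alpha-amino acid 1, aminobenzoic 0.5)
ALK	0.912	1	dummy: pure alkane/alkene hydrocarbon
RNG	-0.392	1	dummy: rings other than benzene and condensed aromatic carbocycles
QN	-3.684	1	quaternary nitrogen
NO2	0.474	1	count of nitro groups
NCS	1.582	1	isothiocyanate/thiocyanate groups
BLM	0.773	1	dummy: beta-lactam
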