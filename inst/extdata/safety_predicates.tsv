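sequence	allergenic	toxic
AK	0	0
AY	0	0
CF	0	0
DL	0	0
EF	0	0
GIL	0	0
GM	0	0
IAL	0	0
IL	0	0
SL	0	0
TF	0	0
TY	0	0
VF	0	0
VL	0	0
VY	0	0
ASL	0	0
ITF	0	0
IVR	0	0
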