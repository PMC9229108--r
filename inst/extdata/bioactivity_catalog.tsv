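sequence	activity	status	source_id	probability	notes
AY	anti-ACE	known	BIOPEP-UWM
CF	anti-ACE	known	BIOPEP-UWM
EF	anti-ACE	known	BIOPEP-UWM
GM	anti-ACE	known	BIOPEP-UWM
IL	anti-ACE	known	BIOPEP-UWM
TF	anti-ACE	known	BIOPEP-UWM
VF	anti-ACE	known	BIOPEP-UWM
VY	anti-ACE	known	BIOPEP-UWM
ASL	anti-ACE	known	BIOPEP-UWM		low GI absorption exemplar
ITF	anti-ACE	known	BIOPEP-UWM		low GI absorption exemplar
IVR	anti-ACE	known	BIOPEP-UWM		low GI absorption exemplar
AY	anti-DPP-IV	known	BIOPEP-UWM
IL	anti-DPP-IV	known	BIOPEP-UWM
SL	anti-DPP-IV	known	BIOPEP-UWM
TF	anti-DPP-IV	known	BIOPEP-UWM
TY	anti-DPP-IV	known	BIOPEP-UWM
VF	anti-DPP-IV	known	BIOPEP-UWM
VL	anti-DPP-IV	known	BIOPEP-UWM
VY	anti-DPP-IV	known	BIOPEP-UWM
GIL	anti-ACE	predicted	SwissTargetPrediction	0.5345
DL	anti-ACE	predicted	SwissTargetPrediction	0.0580
AK	anti-ACE	predicted	SwissTargetPrediction	0.0524
IAL	anti-DPP-IV	predicted	SwissTargetPrediction	0.5776
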