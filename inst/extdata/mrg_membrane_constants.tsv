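parameter	value	units
rhoa	70	ohm_cm
cm_axolemma	2	uF_per_cm2
g_mysa	0.001	S_per_cm2
g_flut	0.0001	S_per_cm2
g_stin	0.0001	S_per_cm2
e_pas	-80	mV
mycm	0.1	uF_per_cm2_per_lamella_membrane
mygm	0.001	S_per_cm2_per_lamella_membrane
gnaf	3.0	S_per_cm2
gnap	0.01	S_per_cm2
gks	0.08	S_per_cm2
gl	0.007	S_per_cm2
ena	50	mV
ek	-90	mV
el	-90	mV
vrest	-80	mV
temperature	36	degC
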