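tf_id	name	kind	model	threshold
AT5G13790	AGL15	consensus	CARGNCAT	0.85
SYNTF01	SYN_TF01	matrix	A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1	0.85
SYNTF02	SYN_TF02	matrix	A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.7,C:0.1,G:0.1,T:0.1	0.85
SYNTF03	SYN_TF03	matrix	A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1	0.85
SYNTF04	SYN_TF04	matrix	A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1	0.85
SYNTF05	SYN_TF05	matrix	A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1	0.85
SYNTF06	SYN_TF06	matrix	A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7	0.85
SYNTF07	SYN_TF07	matrix	A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1	0.85
SYNTF08	SYN_TF08	matrix	A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1	0.85
SYNTF09	SYN_TF09	matrix	A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1	0.85
SYNTF10	SYN_TF10	matrix	A:0.1,C:0.1,G:0.7,T:0.1;A:0.1,C:0.1,G:0.7,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1;A:0.1,C:0.7,G:0.1,T:0.1;A:0.1,C:0.1,G:0.1,T:0.7;A:0.1,C:0.7,G:0.1,T:0.1;A:0.7,C:0.1,G:0.1,T:0.1	0.85
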