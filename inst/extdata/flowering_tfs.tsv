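tf_id	name
AT5G13790	AGL15
SYNTF01	SYN_TF01
SYNTF04	SYN_TF04
SYNTF07	SYN_TF07
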