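gene_id	chromosome	tss_genomic	strand
LalbFTa1	Lalb_Chr02	14996788	forward
LalbFTa2	Lalb_Chr21	12758313	reverse_complement
LalbFTc1	Lalb_Chr14	5850617	forward
LalbFTc2	Lalb_Chr09	7814590	reverse_complement
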