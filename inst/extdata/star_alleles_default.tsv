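rsid	variant_allele	star_tag
rs4244285	A	*2
rs4986893	A	*3
rs17884712	A	*9
rs12248560	T	*17
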