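rsid	chrom	pos	ref	alt	gene	role	star_tag
rs2860840	chr10	94735475	C	T	CYP2C18	cyp2c_site	NA
rs11188059	chr10	94709142	G	A	CYP2C18	cyp2c_site	NA
rs4244285	chr10	94781859	G	A	CYP2C19	star_site	*2
rs4986893	chr10	94780653	G	A	CYP2C19	star_site	*3
rs17884712	chr10	94775489	G	A	CYP2C19	star_site	*9
rs12248560	chr10	94761900	C	T	CYP2C19	star_site	*17
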