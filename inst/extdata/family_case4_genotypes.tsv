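individual_id	gene	hgvs_c	genotype
proband	MYO7A	c.2311G>T	het
proband	PCDH15	c.158-1G>A	het
mother	MYO7A	c.2311G>T	het
mother	PCDH15	c.158-1G>A	ref
father	MYO7A	c.2311G>T	ref
father	PCDH15	c.158-1G>A	het
brother1	MYO7A	c.2311G>T	het
brother1	PCDH15	c.158-1G>A	ref
brother2	MYO7A	c.2311G>T	ref
brother2	PCDH15	c.158-1G>A	ref
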