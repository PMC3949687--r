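patient_id	gene	hgvs_c	hgvs_p	zygosity
1	MYO7A	c.1477C>T	p.Gln493X	het
1	MYO7A	c.4482_4483insTG	p.Trp1495CysfsX55	het
2	MYO7A	c.6205_6206delAT	p.Ile2069ProfsX6	hom
5	MYO7A	c.2074G>A	p.Val692Met	hom
6	MYO7A	c.1708C>T	p.Arg570X	hom
8	MYO7A	c.1623dup	p.Lys542GlnfsX5	hom
11	MYO7A	c.6028G>A	p.Asp2010Asn	het
11	MYO7A	c.6321G>A	p.Trp2107X	het
17	MYO7A	c.2115C>A	p.Cys705X	hom
7	CDH23	c.3567delG	p.Arg1189ArgfsX5	hom
9	CDH23	c.5780_5781delCT	p.Ser1927CysfsX16	het
9	CDH23	c.5821-2A>G	?	het
15	CDH23	c.6319C>T	p.Arg2107X	hom
3	PCDH15	c.3337G>T	p.Glu1113X	hom
16	PCDH15	c.2971C>T	p.Arg991X	hom
10	PCDH15	c.2884C>T	p.Arg962Cys	het
12	PCDH15	c.1006C>T	p.Arg336X	het
13	PCDH15	c.3724G>A	p.Val1242Met	het
4	MYO7A	c.2311G>T	p.Ala771Ser	het
4	PCDH15	c.158-1G>A	?	het
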