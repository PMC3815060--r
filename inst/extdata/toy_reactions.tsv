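reaction_id	equation	gene_association
r01	GLCxt -> G6P	HXK1 or HXK2
r02	G6P -> F6P	PGI1
r03	F6P -> FBP	PFK1 and PFK2
r04	FBP -> DHAP + GAP	FBA1
r05	DHAP <=> GAP	TPI1
r06	GAP -> PEP	TDH1 or (TDH2 and TDH3)
r07	PEP -> PYR	PYK1
r08	PYR -> ACA	PDC1
r09	ACA -> ETH	ADH1
r10	2 PYR -> ACLAC	
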