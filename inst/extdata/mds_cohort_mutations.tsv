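sample	gene	cdna_change	protein_change	mutation_type	vaf_pct	cosmic_id
#132	DNMT3A	c.1961G>A	p.Gly654Asp	missense	73.5	NA
#217	TET2	c.1648C>T	p.Arg550*	nonsense	96.5	COSM41644
#033	TET2	c.3851C>T	p.Ser1284Phe	missense	3.5	COSM120177
#140	TET2	c.5562delT	p.Leu1855Trpfs*32	frameshift	89	NA
#074	TP53	c.824G>A	p.Cys275Tyr	missense	52	COSM165084
#172	TP53	c.583A>T	p.Ile195Phe	missense	76.5	COSM129840
#130	TP53	c.821T>A	p.Val274Asp	missense	45	COSM165076
#171	TP53	c.659A>C	p.Tyr220Ser	missense	54	COSM251427
#072	TP53	c.395A>G	p.Lys132Arg	missense	92.5	COSM308311
#027	TP53	c.406C>T	p.Gln136*	nonsense	46.5	COSM126985
#027	TP53	c.833C>T	p.Pro278Leu	missense	43.5	COSM129831
#026	TP53	c.499C>T	p.Gln167*	nonsense	93.5	COSM121081
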