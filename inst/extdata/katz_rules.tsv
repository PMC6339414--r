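item	block	weight	points	c1_concept	c1_scope	c1_qualifier	c1_course	c2_concept	c2_scope	c2_qualifier
bathing	bathing	1	1	112441	subtree	able
bathing	bathing	1	0	112441	subtree	unable
dressing	dressing	1	1	112442	subtree	able
dressing	dressing	1	0	112442	subtree	unable
toileting	toileting	1	1	112444	subtree	able
toileting	toileting	1	0	112444	subtree	unable
feeding	feeding	1	1	112445	subtree	able
feeding	feeding	1	0	112445	subtree	unable
transfer	transfer	1	1	1122	subtree	able
transfer	transfer	1	0	1122	subtree	unable
continence	continence	1	1	11272	cont-both	any
continence	continence	1	0	11271	incont-either	unqualified
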