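item	block	weight	points	c1_concept	c1_scope	c1_qualifier	c1_course	c2_concept	c2_scope	c2_qualifier
continence	continence	1	2	11272	cont-both	any
continence	continence	1	0	11271	incont-either	unqualified
personal_care_bathing	personal_care_bathing	1	2	112441	subtree	unqualified|able
personal_care_bathing	personal_care_bathing	1	1	112441	subtree	with-difficulty
personal_care_bathing	personal_care_bathing	1	0	112441	subtree	unable
personal_care_dressing	personal_care_dressing	1	2	112442	subtree	unqualified|able
personal_care_dressing	personal_care_dressing	1	1	112442	subtree	with-difficulty
personal_care_dressing	personal_care_dressing	1	0	112442	subtree	unable
personal_care_grooming	personal_care_grooming	1	2	112443	subtree	unqualified|able
personal_care_grooming	personal_care_grooming	1	1	112443	subtree	with-difficulty
personal_care_grooming	personal_care_grooming	1	0	112443	subtree	unable
personal_care_toileting	personal_care_toileting	1	2	112444	subtree	unqualified|able
personal_care_toileting	personal_care_toileting	1	1	112444	subtree	with-difficulty
personal_care_toileting	personal_care_toileting	1	0	112444	subtree	unable
personal_care_feeding	personal_care_feeding	1	2	112445	subtree	unqualified|able
personal_care_feeding	personal_care_feeding	1	1	112445	subtree	with-difficulty
personal_care_feeding	personal_care_feeding	1	0	112445	subtree	unable
transfer	transfer	1	2	1122	subtree	any
transfer	transfer	1	0	1122	subtree	absent
transfer	transfer	1	0	1122	subtree	unable
mobility	mobility	1	3	112121	subtree	able
mobility	mobility	1	3	112472	subtree	any
mobility	mobility	1	2	112121	subtree	with-difficulty
mobility	mobility	1	2	112473	subtree	any
mobility	mobility	1	1	1121223	subtree	any
mobility	mobility	1	0	112121	subtree	unable
mobility	mobility	1	0	1121221	subtree	any
stairs	stairs	1	2	1124713	subtree	able
stairs	stairs	1	2	1124711	subtree	able
stairs	stairs	1	0	1124713	subtree	unable
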