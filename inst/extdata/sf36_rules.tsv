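item	block	weight	points	c1_concept	c1_scope	c1_qualifier	c1_course	c2_concept	c2_scope	c2_qualifier
general_health	gh_q1_33_36	1	100	1323	subtree	unqualified|high-frequency
general_health	gh_q1_33_36	1	75	1323	subtree	mid-frequency
general_health	gh_q1_33_36	1	50	1324	subtree	absent
general_health	gh_q1_33_36	1	25	1324	subtree	mid-frequency
general_health	gh_q1_33_36	1	0	1324	subtree	unqualified|high-frequency
general_health	gh_q2	1	100	1323	subtree	unqualified|high-frequency	sudden-onset
general_health	gh_q2	1	75	1323	subtree	mid-frequency	sudden-onset
general_health	gh_q2	1	50	1324	subtree	absent
general_health	gh_q2	1	25	1324	subtree	mid-frequency
general_health	gh_q2	1	0	1324	subtree	unqualified|high-frequency
pain	pain_q21	1	100	1111	subtree	absent
pain	pain_q21	1	50	1111	subtree	mid-frequency
pain	pain_q21	1	0	1111	subtree	high-frequency
pain	pain_q22	1	100	1111	subtree	absent		11245	subtree	able
pain	pain_q22	1	75	1111	subtree	mid-frequency		11245	subtree	able
pain	pain_q22	1	50	1111	subtree	high-frequency		11245	subtree	able
pain	pain_q22	1	25	1111	subtree	mid-frequency		11245	subtree	with-difficulty
pain	pain_q22	1	0	1111	subtree	high-frequency		11245	subtree	unable|with-difficulty
physical_functioning	pf_q3	1	100	11233	subtree	high-frequency
physical_functioning	pf_q3	1	100	11213	subtree	able
physical_functioning	pf_q3	1	50	11233	subtree	mid-frequency
physical_functioning	pf_q3	1	0	11234	subtree	any
physical_functioning	pf_q3	1	0	11213	subtree	unable
physical_functioning	pf_q3	1	0	11233	subtree	absent
physical_functioning	pf_q4	1	100	11232	subtree	high-frequency
physical_functioning	pf_q4	1	50	11232	subtree	mid-frequency
physical_functioning	pf_q4	1	0	11234	subtree	any
physical_functioning	pf_q4	1	0	11213	subtree	unable
physical_functioning	pf_q4	1	0	11232	subtree	absent
physical_functioning	pf_q5	1	100	11243	subtree	able
physical_functioning	pf_q5	1	100	112413	subtree	able
physical_functioning	pf_q5	1	50	11243	subtree	with-difficulty
physical_functioning	pf_q5	1	50	112413	subtree	with-difficulty
physical_functioning	pf_q5	1	0	11243	subtree	unable
physical_functioning	pf_q5	1	0	112413	subtree	unable
physical_functioning	pf_q6_7	2	200	1124713	subtree	able
physical_functioning	pf_q6_7	2	100	1124713	subtree	with-difficulty
physical_functioning	pf_q6_7	2	0	1124713	subtree	unable
physical_functioning	pf_q8	1	100	11211	subtree	able
physical_functioning	pf_q8	1	50	11211	subtree	with-difficulty
physical_functioning	pf_q8	1	0	11211	subtree	unable
physical_functioning	pf_q9_11	3	300	112471	self	able
physical_functioning	pf_q9_11	3	200	112471	self	with-difficulty
physical_functioning	pf_q9_11	3	0	112471	self	unable
physical_functioning	pf_q12	1	100	11244	self	able
physical_functioning	pf_q12	1	50	11244	self	with-difficulty
physical_functioning	pf_q12	1	0	11244	self	unable
role_physical	rp_q13_15	3	300	1154	subtree	absent
role_physical	rp_q13_15	3	150	1154	subtree	mid-frequency
role_physical	rp_q13_15	3	0	1154	subtree	high-frequency
role_physical	rp_q16	1	100	11245	subtree	able
role_physical	rp_q16	1	50	11245	subtree	with-difficulty
role_physical	rp_q16	1	0	11245	subtree	unable
role_emotional	re_q17_19	3	300	1154	subtree	absent		113	subtree	any
role_emotional	re_q17_19	3	150	1154	subtree	mid-frequency		113	subtree	any
role_emotional	re_q17_19	3	0	1154	subtree	high-frequency		113	subtree	any
energy_fatigue	ef_q23_31	1	100	132221	subtree	able
energy_fatigue	ef_q23_31	1	100	132222	subtree	absent
energy_fatigue	ef_q23_31	1	50	132221	subtree	with-difficulty
energy_fatigue	ef_q23_31	1	50	132222	subtree	mid-frequency
energy_fatigue	ef_q23_31	1	0	132221	subtree	unable
energy_fatigue	ef_q23_31	1	0	132222	subtree	high-frequency
emotional_wellbeing	ew_q24_26	2	200	113331	subtree	high-frequency
emotional_wellbeing	ew_q24_26	2	200	113333	subtree	absent
emotional_wellbeing	ew_q24_26	2	200	21	subtree	absent
emotional_wellbeing	ew_q24_26	2	150	113331	subtree	mid-frequency
emotional_wellbeing	ew_q24_26	2	100	113333	subtree	mid-frequency
emotional_wellbeing	ew_q24_26	2	50	113331	subtree	absent
emotional_wellbeing	ew_q24_26	2	0	113333	subtree	high-frequency
emotional_wellbeing	ew_q24_26	2	0	21	subtree	unqualified|high-frequency
emotional_wellbeing	ew_q25_30	3	300	113332	subtree	high-frequency
emotional_wellbeing	ew_q25_30	3	300	113334	subtree	absent
emotional_wellbeing	ew_q25_30	3	300	22	subtree	absent
emotional_wellbeing	ew_q25_30	3	225	113332	subtree	mid-frequency
emotional_wellbeing	ew_q25_30	3	150	113334	subtree	mid-frequency
emotional_wellbeing	ew_q25_30	3	75	113332	subtree	absent
emotional_wellbeing	ew_q25_30	3	0	113334	subtree	high-frequency
emotional_wellbeing	ew_q25_30	3	0	22	subtree	unqualified|high-frequency
social_functioning	sf_q32	1	100	11241	self	able
social_functioning	sf_q32	1	50	11241	self	with-difficulty
social_functioning	sf_q32	1	0	11241	self	unable
social_functioning	sf_q20	1	100	11531	subtree	absent
social_functioning	sf_q20	1	50	11531	subtree	mid-frequency
social_functioning	sf_q20	1	0	11531	subtree	high-frequency
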