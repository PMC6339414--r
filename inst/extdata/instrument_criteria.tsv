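instrument	aliases	scale_min	scale_max	lo	hi	label	indication	direction	caution	notes
adl_screen	ADL screen;activities of daily living screen	0	18	18	18	patient independent	not-frail-indicative	lower-is-frailer	TRUE	printed criteria internally inconsistent; interpret with caution
adl_screen	ADL screen;activities of daily living screen	0	18	6	6	patient very independent	not-frail-indicative	lower-is-frailer	TRUE	printed criteria internally inconsistent; interpret with caution
fim	FIM;functional independence measure	1	7	7	7	complete independence	not-frail-indicative	lower-is-frailer	FALSE
fim	FIM;functional independence measure	1	7	6	6	modified independence	intermediate	lower-is-frailer	FALSE
fim	FIM;functional independence measure	1	7	5	5	supervision or step-up	intermediate	lower-is-frailer	FALSE
fim	FIM;functional independence measure	1	7	4	4	minimal contact assistance	intermediate	lower-is-frailer	FALSE
fim	FIM;functional independence measure	1	7	3	3	moderate assistance	intermediate	lower-is-frailer	FALSE
fim	FIM;functional independence measure	1	7	2	2	maximal assistance	intermediate	lower-is-frailer	FALSE
fim	FIM;functional independence measure	1	7	1	1	total assistance	frail-indicative	lower-is-frailer	FALSE
katz	Katz index ADL;Katz ADL;Katz index;Katz	0	6	6	6	high functioning, patient is independent	not-frail-indicative	lower-is-frailer	FALSE
katz	Katz index ADL;Katz ADL;Katz index;Katz	0	6	1	5	intermediate dependence	intermediate	lower-is-frailer	FALSE	interval between the two published anchors
katz	Katz index ADL;Katz ADL;Katz index;Katz	0	6	0	0	low, patient is very dependent	frail-indicative	lower-is-frailer	FALSE
barthel100	Barthel index;Barthel	0	100	70	100	independent	not-frail-indicative	lower-is-frailer	FALSE	0-100 scale variant; distinct from the 0-20 rule-based scorer
barthel100	Barthel index;Barthel	0	100	0	69	needs significant physical/supervisory assistance	frail-indicative	lower-is-frailer	FALSE	0-100 scale variant; distinct from the 0-20 rule-based scorer
iadl_item	IADL item	0	2	2	2	without assistance	not-frail-indicative	lower-is-frailer	FALSE	per-item scoring
iadl_item	IADL item	0	2	1	1	with assistance	intermediate	lower-is-frailer	FALSE	per-item scoring
iadl_item	IADL item	0	2	0	0	unable	frail-indicative	lower-is-frailer	FALSE	per-item scoring
lawton	Lawton;IADL scale;IADL screen;IADL	0	8	0	8	total score; lower score indicates higher dependence	unmapped	lower-is-frailer	TRUE	direction-only criteria; no published category cut points
faq	FAQ;functional activity questionnaire;functional activities questionnaire	0	30	5	30	significant impairment in instrumental activities of daily living	frail-indicative	higher-is-frailer	FALSE
faq	FAQ;functional activity questionnaire;functional activities questionnaire	0	30	0	4	below impairment threshold	not-frail-indicative	higher-is-frailer	FALSE	complement of the published cut point
morse	Morse fall scale;annual fall scale;MRT;Morse	0	125	45	125	high fall risk	frail-indicative	higher-is-frailer	FALSE
morse	Morse fall scale;annual fall scale;MRT;Morse	0	125	25	44	moderate risk	intermediate	higher-is-frailer	FALSE
morse	Morse fall scale;annual fall scale;MRT;Morse	0	125	0	24	low risk	not-frail-indicative	higher-is-frailer	FALSE
tinetti	Tinetti assessment measures;Tinetti	0	28	0	18	high risk for falls	frail-indicative	lower-is-frailer	FALSE	balance max 16; gait max 12; total max 28
tinetti	Tinetti assessment measures;Tinetti	0	28	19	24	some risk for falls	intermediate	lower-is-frailer	FALSE	balance max 16; gait max 12; total max 28
tinetti	Tinetti assessment measures;Tinetti	0	28	25	28	low risk for falls	not-frail-indicative	lower-is-frailer	FALSE	complement of the published cut points
braden	Braden scale;Braden	6	23	6	9	very high risk	frail-indicative	lower-is-frailer	FALSE	pressure ulcer risk
braden	Braden scale;Braden	6	23	10	12	high risk	intermediate	lower-is-frailer	FALSE	pressure ulcer risk
braden	Braden scale;Braden	6	23	13	14	moderate risk	intermediate	lower-is-frailer	FALSE	pressure ulcer risk
braden	Braden scale;Braden	6	23	15	18	mild risk	intermediate	lower-is-frailer	FALSE	pressure ulcer risk
braden	Braden scale;Braden	6	23	19	23	no risk	not-frail-indicative	lower-is-frailer	FALSE	pressure ulcer risk
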