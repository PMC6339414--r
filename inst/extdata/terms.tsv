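surface	ccfo_id
pain	1111
calm	113331
happy	113332
nervous	113333
sad	113334
tearful	113334
isolated	11531
socially isolated	11531
limited at work	1154
off work	1154
kneel	11211
kneeling	11211
ambulate independently	112121
steady gait	112121
unsteady gait	112121
bed-ridden	1121221
stretcher	1121221
paralysis	1121222
paralyzed	1121222
wheelchair	1121223
scooter	1121223
w/c	1121223
wheel chair	1121223
difficulty running	11213
able to run	11213
unable to run	11213
run	11213
difficulty standing up	11214
unable to stand up	11214
able to stand up	11214
stand up	11214
stand	11214
transfers	1122
transfer	1122
light exercise	11231
moderate exercise	11232
vigorous exercise	11233
sedentary	11234
errands	11241
driving	112411
drives	112411
leisure activities	112412
hobbies	112412
shopping	112413
grocery shopping	112413
physical activity	11243
personal care	11244
bathes	112441
bathing	112441
dresses	112442
able to dress	112442
independent with dressing	112442
needs help with dressing	112442
dependent for dressing	112442
unable to dress	112442
difficulty dressing	112442
shoes	112442
ties shoes	112442
able to wash own hair	112443
unable to wash own hair	112443
difficulty washing own hair	112443
clean appearance	112443
personal grooming	112443
neatly dressed	112443
well-groomed	112443
well-groomed without assistance	112443
good personal hygiene	112443
toileting	112444
feeds self	112445
daily routine	11245
walks	112471
walk	112471
downstairs	1124711
upstairs	1124713
stairs	1124713
unaided ambulation	112472
cane	112473
walker	112473
walking aid	112473
prosthetics	112473
oral intake	11251
incontinent	11271
incontinent of urine	112711
incontinent of stool	112712
continent	11272
continent of urine	112721
continent of stool	112722
sob	131
short of breath	131
dyspnea	131
comorbidities	1325
multiple comorbidities	1325
good stamina	132221
lack of energy	132222
tired	132222
fatigue	132222
lack energy	132222
tiredness	132222
sleepiness	132222
drowsiness	132222
exhaustion	132222
exhaust	132222
wear out	132222
drain	132222
weary	132222
fit and well	1323
robust	1323
unwell	1324
generally unwell	1324
weakness	133
muscle strength	133
motor strength	133
decreased strength	133
gripping strength	133
calf weakness	1331
weak calves	1331
quadriceps weakness	1334
quad weakness	1334
deconditioned	134
deconditioning	134
bmi	135
low body weight	135
stagger	136
staggering	136
loses balance	136
anxiety	21
anxious	21
depression	22
depressed	22
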