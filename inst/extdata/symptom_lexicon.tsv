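canonical_symptom	synonym
exophthalmos	exophthalmos
exophthalmos	bulging eyes
pyrosis	pyrosis
pyrosis	heartburn
hallucination	hallucination
hallucination	hallucinations
hallucination	seeing things
impotence	impotence
impotence	erectile dysfunction
back pain	back pain
back pain	back ache
back pain	backache
urticaria	urticaria
urticaria	hives
akathisia	akathisia
akathisia	inner restlessness
diaphoresis	diaphoresis
diaphoresis	sweating
diaphoresis	night sweats
agoraphobia	agoraphobia
agoraphobia	fear of open spaces
cataplexy	cataplexy
bloating	bloating
bloating	bloated
blindness	blindness
blindness	going blind
amnesia	amnesia
amnesia	memory loss
dizziness	dizziness
dizziness	dizzy
dizziness	lightheaded
anxiety	anxiety
anxiety	anxious
blister	blister
blister	blisters
blurred vision	blurred vision
blurred vision	blurry vision
itch	itch
itch	itching
itch	itchy
swelling	swelling
swelling	swollen
tinnitus	tinnitus
tinnitus	ears ringing
tinnitus	ringing in ears
anorexia	anorexia
anorexia	loss of appetite
cough	cough
cough	coughing
cramp	cramp
cramp	cramps
cramp	cramping
depression	depression
depression	depressed
pain	pain
weight loss	weight loss
weight loss	losing weight
deformity	deformity
paresthesia	paresthesia
paresthesia	skin crawling
paresthesia	pins and needles
diarrhea	diarrhea
diarrhea	diarrhoea
malaise	malaise
malaise	feeling unwell
phobia	phobia
fatigue	fatigue
fatigue	tired
fatigue	exhausted
constipation	constipation
constipation	constipated
fever	fever
fever	high temperature
dysphagia	dysphagia
dysphagia	trouble swallowing
dysphagia	difficulty swallowing
paranoia	paranoia
paranoia	paranoid
perspiration	perspiration
rash	rash
rash	skin rash
toothache	toothache
toothache	tooth ache
xerostomia	xerostomia
xerostomia	dry mouth
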