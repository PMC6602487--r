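# NegEx regression cases: sentence<TAB>target surface<TAB>expected negated (1/0)
# The target is the first occurrence of the surface in the sentence; cases
# exercise PRE_NEG, POST_NEG, PSEUDO_NEG masking, TERMINATION blocking,
# sentence bounding and the 5-token window of the bundled trigger set.
Patient denies fever.	fever	1
Patient has fever.	fever	0
No rash noted.	rash	1
There was no increase in pain.	pain	0
Has fever but no cough.	fever	0
Has fever but no cough.	cough	1
Without headache today.	headache	1
Seizure was ruled out.	Seizure	1
Seizure not ruled out.	Seizure	0
Fracture is unlikely.	Fracture	1
No evidence of jaundice.	jaundice	1
Negative for edema.	edema	1
Never had seizures before.	seizures	1
Gram negative rods in culture.	rods	0
No report of any acute or chronic headache.	headache	0
No acute headache.	headache	1
Denies chest pain and palpitations.	palpitations	1
Denies chest pain and palpitations.	chest pain	1
Has rash; no fever.	rash	0
Has rash; no fever.	fever	1
Not only anemia was found.	anemia	0
Cough has resolved.	Cough	1
No weight loss, although fatigue persists.	fatigue	0
No weight loss, although fatigue persists.	weight loss	1
Lungs clear, free of wheezing.	wheezing	1
Headache was absent.	Headache	1
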