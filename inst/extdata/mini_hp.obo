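format-version: 1.2
ontology: mini-hp-fixture

[Term]
id: HP:5000001
name: Phenotypic abnormality (fixture root)

[Term]
id: HP:5000002
name: Short stature
synonym: "Decreased body height" EXACT []
xref: UMLS:C0349588
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000003
name: Abnormal stature
synonym: "Stature" RELATED []
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000004
name: Abnormality of the kidney
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000005
name: Abnormality of the vasculature
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000006
name: Renal hypertension
xref: UMLS:C1306620
is_a: HP:5000004 ! Abnormality of the kidney
is_a: HP:5000005 ! Abnormality of the vasculature

[Term]
id: HP:5000007
name: Fever
synonym: "Febrile episode" BROAD []
xref: UMLS:C0015967
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000008
name: Hyperthermia
xref: UMLS:C0015967
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000009
name: Cough
synonym: "Tussis" EXACT []
synonym: "Chronic cough" NARROW []
is_a: HP:5000001 ! Phenotypic abnormality (fixture root)

[Term]
id: HP:5000010
name: Dyspnea
is_obsolete: true

[Term]
id: HP:5000011
name: Seizure
is_obsolete: true

[Term]
id: HP:5000012
name: Mode of inheritance (fixture)

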