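subject	subject_type	predicate	object	object_type	pmid
aspirin	Chemicals & Drugs	TREATS	headache	Disorders	PM01
aspirin	Chemicals & Drugs	TREATS	headache	Disorders	PM02
aspirin	Chemicals & Drugs	PREVENTS	myocardial_infarction	Disorders	PM03
aspirin	Chemicals & Drugs	PREVENTS	myocardial_infarction	Disorders	PM04
ibuprofen	Chemicals & Drugs	TREATS	headache	Disorders	PM05
ibuprofen	Chemicals & Drugs	TREATS	headache	Disorders	PM06
ibuprofen	Chemicals & Drugs	TREATS	migraine_classic	Disorders	PM07
ibuprofen	Chemicals & Drugs	TREATS	migraine_common	Disorders	PM08
aspirin	Chemicals & Drugs	RELATED_TO	ibuprofen	Chemicals & Drugs	PM09
aspirin	Chemicals & Drugs	RELATED_TO	ibuprofen	Chemicals & Drugs	PM10
headache	Disorders	ASSOCIATED_WITH	migraine_classic	Disorders	PM11
headache	Disorders	ASSOCIATED_WITH	migraine_classic	Disorders	PM12
naproxen	Chemicals & Drugs	RELATED_TO	ibuprofen	Chemicals & Drugs	PM13
naproxen	Chemicals & Drugs	RELATED_TO	ibuprofen	Chemicals & Drugs	PM14
naproxen	Chemicals & Drugs	TREATS	arthritis	Disorders	PM15
naproxen	Chemicals & Drugs	INHIBITS	arthritis	Disorders	PM16
caffeine	Chemicals & Drugs	AFFECTS	headache	Disorders	PM17
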