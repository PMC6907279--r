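drug	disease	approval_year
aspirin	headache	1950
ibuprofen	headache	1974
ibuprofen	migraine	1989
naproxen	arthritis	1976
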