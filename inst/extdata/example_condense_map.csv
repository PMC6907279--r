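source_type,predicate,target_type,replacement
Chemicals & Drugs,PREVENTS,Disorders,TREATS
Chemicals & Drugs,INHIBITS,Disorders,TREATS
Chemicals & Drugs,AFFECTS,Disorders,DROP
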