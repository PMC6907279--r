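raw_id,canonical_id,canonical_name
migraine_classic,migraine,Migraine
migraine_common,migraine,Migraine
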