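concept_id,concept_name
4241223,hidradenitis suppurativa
434119,hidradenitis
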