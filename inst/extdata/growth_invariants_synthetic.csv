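component,term,estimate,sd
fixed,invariant_long,1,NA
fixed,invariant_short,1.05,NA
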