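component,term,estimate,sd
fixed,intercept,-0.2750,NA
fixed,log_rmax,-0.5851,NA
random,residual,0,0.96
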