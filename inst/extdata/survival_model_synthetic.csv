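component,term,estimate,sd
fixed,intercept,2.3076,NA
fixed,log_mass,0.3922,NA
fixed,alpha,-0.1104,NA
random,taxon,0,0.2828
random,residual,0,0.2828
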