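constant,value
delta,1.90
rho,0.50
gamma,0.50
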