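vegetation_type,mean_biomass_t_per_hm2,CF
economic,23.70,0.47
shrub,19.76,0.47
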