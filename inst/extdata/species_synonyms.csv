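field,token,canonical
species,k_fortunei,K_fortunei
species,keteleeria fortunei,K_fortunei
species,keteleeria,K_fortunei
species,p_armandii,P_armandii
species,pinus armandii,P_armandii
species,armand pine,P_armandii
species,p_yunnanensis,P_yunnanensis
species,pinus yunnanensis,P_yunnanensis
species,yunnan pine,P_yunnanensis
species,c_funebris,C_funebris
species,cupressus funebris,C_funebris
species,chinese weeping cypress,C_funebris
species,quercus_sp,Quercus_sp
species,quercus sp,Quercus_sp
species,quercus,Quercus_sp
species,oak,Quercus_sp
species,e_robusta,E_robusta
species,eucalyptus robusta,E_robusta
species,eucalyptus,E_robusta
species,a_cremastogyne,A_cremastogyne
species,alnus cremastogyne,A_cremastogyne
species,alder,A_cremastogyne
species,economic_mixed,economic_mixed
species,economic,economic_mixed
species,orchard,economic_mixed
species,shrub_mixed,shrub_mixed
species,shrub,shrub_mixed
species,none,none
species,na,none
vegetation_type,arbor,arbor
vegetation_type,arbor forest,arbor
vegetation_type,tree,arbor
vegetation_type,economic,economic
vegetation_type,economic forest,economic
vegetation_type,shrub,shrub
vegetation_type,shrubland,shrub
vegetation_type,shrub forest,shrub
vegetation_type,non_stocked,non_stocked
vegetation_type,non-stocked,non_stocked
vegetation_type,unstocked,non_stocked
age_group,young,young
age_group,young forest,young
age_group,middle_aged,middle_aged
age_group,middle-aged,middle_aged
age_group,middle aged forest,middle_aged
age_group,mid,middle_aged
age_group,near_mature,near_mature
age_group,near-mature,near_mature
age_group,near mature forest,near_mature
age_group,mature,mature
age_group,mature forest,mature
age_group,not_applicable,not_applicable
age_group,na,not_applicable
zone,core,core
zone,core zone,core
zone,buffer,buffer
zone,buffer zone,buffer
zone,experimental,experimental
zone,experimental zone,experimental
zone,experiment,experimental
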