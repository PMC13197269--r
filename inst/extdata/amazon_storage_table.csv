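tree_id,species,group,theta_t,theta_d,theta_mean,theta_sd,diurnal_delta,wood_density,height,dbh
AV,Astrocaryum vulgare,palm,0.673,0.436,0.532,0.089,0.058,0.63,20,0.22
OD,Oenocarpus distichus,palm,0.728,0.521,0.674,0.063,0.038,0.29,13,0.22
PT,Protium tenuifolium,dicot,0.459,0.367,0.397,0.025,0.028,0.54,,
VA,Vouacapoua americana,dicot,0.391,0.300,0.333,0.026,0.025,0.82,,
LO,Licania octandra,dicot,0.485,0.400,0.427,0.021,0.012,0.69,,
PD1,Pouteria decorticans,dicot,0.366,0.306,0.326,0.018,0.016,0.75,,
PD2,Pouteria decorticans,dicot,0.352,0.292,0.315,0.016,0.013,0.75,,
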