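drug,annual_cost_gov,annual_cost_patient,note
diuretic,52.03,18.79,low-dose diuretic PBS 2008 script-weighted annual cost
calcium_channel_blocker,163.66,54.22,PBS 2008 script-weighted annual cost
ace_inhibitor,130.85,81.21,PBS 2008 script-weighted annual cost
beta_blocker,169.59,47.09,published source note for this row duplicates the statin drug list (apparent copy error); prices used as printed
statin,508.64,178.79,PBS 2008 script-weighted annual cost
statin_nz,18.25,0,New Zealand price of simvastatin 40 mg/day
current_practice_lipid,559.68,123.37,actual PBS expenditure on lipid-lowering drugs 2008
current_practice_bp,169.59,47.09,actual PBS expenditure on blood pressure-lowering drugs 2008
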