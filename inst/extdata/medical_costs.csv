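pattern,item,gov_price,patient_price,units_year1,units_year2plus
lipid,long_gp_visit,54.19,9.56,1,0
lipid,short_gp_visit,28.52,5.03,0,2
lipid,blood_test,15.13,2.67,1,2
bp,long_gp_visit,54.19,9.56,1,0
bp,short_gp_visit,28.52,5.03,2,2
bp,blood_test,15.13,2.67,3,2
both,long_gp_visit,54.19,9.56,1,0
both,short_gp_visit,28.52,5.03,2,2
both,blood_test,15.13,2.67,4,2
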