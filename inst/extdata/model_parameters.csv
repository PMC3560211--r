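name,mean,se,distribution
rr_stroke_in_ihd_men,1.32,0.20,normal_on_log
rr_stroke_in_ihd_women,1.88,0.30,normal_on_log
rr_ihd_in_stroke_men,2.64,0.07,normal_on_log
rr_ihd_in_stroke_women,2.85,0.04,normal_on_log
ihd_cost_year1,12921,NA,uniform_pm25
ihd_cost_subsequent,4539,NA,uniform_pm25
stroke_cost_year1,23581,NA,uniform_pm25
stroke_cost_subsequent,3201,NA,uniform_pm25
gp_participation,0.65,0.065,beta
discontinuation_year1,0.40,0.08,beta
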