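term,sex,value
intercept,all,18.8144
female,all,-1.2146
log_age,all,-1.8443
female_log_age,all,0.3668
log_sbp,all,-1.4032
smoker,all,-0.3899
log_tc_hdl,all,-0.5390
diabetes,all,-0.3036
female_diabetes,all,-0.1697
lvh,all,-0.3362
theta0,all,0.9145
theta1,all,-0.2784
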