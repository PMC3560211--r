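drug,disease,rr,ci_lower,ci_upper
statin,ihd,0.70,0.61,0.81
diuretic,ihd,0.86,0.75,0.98
calcium_channel_blocker,ihd,0.85,0.78,0.92
ace_inhibitor,ihd,0.83,0.78,0.89
beta_blocker,ihd,0.78,0.89,1.02
statin,stroke,0.81,0.71,0.93
diuretic,stroke,0.62,0.53,0.72
calcium_channel_blocker,stroke,0.66,0.58,0.75
ace_inhibitor,stroke,0.78,0.66,0.92
beta_blocker,stroke,0.70,0.83,0.99
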