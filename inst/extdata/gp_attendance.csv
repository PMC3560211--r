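age_band,male,female
35-44,0.73,0.88
45-54,0.81,0.89
55-64,0.81,0.89
65-74,0.93,0.94
75+,0.99,0.99
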