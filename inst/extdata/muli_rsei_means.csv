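fire,zone,pre_rsei_mean,post_rsei_mean
2019-03-30,heavy,0.6623,0.4928
2019-03-30,mild,0.6674,0.6036
2020-03-28,heavy,0.6953,0.5321
2020-03-28,mild,0.6971,0.5910
2021-04-05,heavy,0.7270,0.4239
2021-04-05,mild,0.7484,0.5894
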