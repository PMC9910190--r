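post,pre_poor,pre_fair,pre_moderate,pre_good,pre_excellent
poor,0,0,0,0,0
fair,0,0,0.09,0,0
moderate,0,0,8.02,34.26,0
good,0,0,0,34.53,0.72
excellent,0,0,0,0,0
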