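fire,reference_heavy_hm2,reference_mild_hm2,reference_total_hm2,extracted_heavy_hm2,extracted_mild_hm2,extracted_total_hm2,dnbr_threshold1,dnbr_threshold2
2019-03-30,43.90,74.19,118.09,43.20,77.62,120.82,0.3010,0.0654
2020-03-28,8856.05,8547.84,17403.89,9574.57,9680.25,19254.82,0.3789,0.1211
2021-04-05,66.12,150.26,216.38,66.81,159.59,226.40,0.4024,0.1464
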