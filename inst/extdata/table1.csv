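density0_mm2,exp_day3_mean,exp_day3_sd,model_day3
305.21,682.81,166.21,516.86
798.74,1375.57,810.3,1339.00
457.92,746.11,20.95,763.38
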