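strain,time_h,exp_mean,exp_sd,model
4-6,24,1.22,0.19,1.44
2-8,24,0.99,0.29,1.04
0-10,24,0.80,0.14,0.87
4-6,72,1.34,0.95,1.37
2-8,72,0.44,0.15,1.08
0-10,72,0.939,0.12,0.83
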