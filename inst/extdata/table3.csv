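source,krot_c,foldchange_72h,sd
model,0,0.88,
model,0.0005,0.92,
model,0.001,0.88,
model,0.01,0.91,
model,0.05,1.03,
experiment,,0.939,0.12
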