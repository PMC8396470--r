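line	height_mean_cm	height_sd_cm
ndf-1	71.4	3.3
ndf-2	86.8	4.9
3529	198.7	15.9
F1	152.1	NA
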