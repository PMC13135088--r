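label,sens_a,spec_a,sens_b,spec_b,net_gain_printed
women_bct_vs_bmd_5yr,81.4,80.0,47.8,92.9,20.7
men_bct_vs_bmd_5yr,66.9,92.2,26.8,98.6,33.7
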