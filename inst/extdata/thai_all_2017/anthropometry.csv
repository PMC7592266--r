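age_band,mean_height_cm,mean_weight_kg
0-4,95,14.5
5-9,125,25
10-14,150,42
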