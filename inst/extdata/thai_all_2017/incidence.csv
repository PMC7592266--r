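year,age_band,diagnosed,diagnosed_lb,diagnosed_ub,undiagnosed,undiagnosed_lb,undiagnosed_ub
2017,0-4,145.962,90,198,98.929892,44,169
2017,5-9,104.304,66,142,70.694999,32,119
2017,10-14,67.734,41,94,45.375109,23,73
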