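case,allred_visual,allred_digital,allred_hsi,h_visual,h_digital,h_hsi
1,2,2,2,2,2,2
2,2,1,1,2,1,1
3,2,1,2,2,1,2
4,2,2,2,2,2,2
5,1,1,1,1,1,1
6,1,1,2,1,1,2
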