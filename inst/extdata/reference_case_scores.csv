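case,h_visual,allred_visual,h_digital,allred_digital,h_hsi,allred_hsi
1,300,8,257.62,8,233.65,7
2,200,7,104.81,6,146.34,6
3,200,7,6.77,3,187.492,7
4,300,8,215.13,8,155.988,7
5,140,6,94.01,6,123.78,6
6,100,6,61.97,5,200.2,7
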