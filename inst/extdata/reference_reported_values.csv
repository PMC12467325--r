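quantity,printed
kappa_allred_visual_digital_cohort,0.677
mean_h_visual,206.67
mean_h_digital,123.38
mean_h_hsi,174.57
mean_allred_visual,7
mean_allred_digital,6
mean_allred_hsi,7
kappa_allred_visual_digital_cases,0.40
kappa_allred_digital_hsi_cases,0.40
kappa_allred_visual_hsi_cases,0.42
kappa_h_visual_digital_cases,0.40
kappa_h_digital_hsi_cases,0.40
kappa_h_visual_hsi_cases,0.42
spearman_h_visual_hsi,0.67
representative_cores,97
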