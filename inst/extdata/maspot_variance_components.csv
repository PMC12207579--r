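trait,sigma2_a,se_a,ve_a_pct,sigma2_f,se_f,ve_f_pct,sigma2_l,se_l,ve_l_pct,sca_gca
dry_matter,2.42,0.19,29.83,0.38,0.08,4.67,4.61,0.11,56.93,0.63
yield,4712.16,2076.41,12.64,1918.28,380.78,5.15,15473.31,1208.25,41.51,1.63
eye_depth,0.08,0.06,13.26,0.05,0.02,7.95,NA,NA,NA,2.40
flesh_color,1.01,0.37,49.11,0.06,0.01,2.94,0.37,0.19,17.83,0.24
skin_finish,0.09,0.03,15.09,0.01,0.004,2.58,0.18,0.02,31.22,0.68
senescence,0.19,0.08,9.12,0.06,0.01,2.76,1.12,0.05,54.66,1.22
tubers_per_plant,7.47,3.03,22.00,1.94,0.37,5.71,14.21,1.61,41.85,1.04
length,58.41,21.78,54.07,2.47,0.60,2.28,21.09,10.99,19.52,0.17
diameter,11.12,4.56,23.10,2.64,0.51,5.49,22.24,2.40,46.22,0.95
length_width_ratio,0.013,0.005,33.58,0.003,0.0005,7.50,0.016,0.003,41.90,0.89
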