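trait,cytoplasm,contrast,se,pct_of_mean
dry_matter,T/b,-2.24,0.62,11.05
dry_matter,D,-1.45,0.64,7.16
yield,T/b,6.48,29.42,1.05
yield,D,-1.88,31.14,0.31
eye_depth,T/b,0.10,0.24,3.56
eye_depth,D,-0.26,0.29,9.85
flesh_color,T/b,0.54,0.39,10.42
flesh_color,D,0.55,0.39,10.60
skin_finish,T/b,0.29,0.12,10.88
skin_finish,D,0.27,0.12,10.08
senescence,T/b,0.40,0.18,6.60
senescence,D,0.16,0.19,2.61
tubers_per_plant,T/b,-0.68,1.12,4.21
tubers_per_plant,D,0.25,1.17,1.54
length,T/b,1.37,2.93,2.09
length,D,-0.16,2.97,0.25
diameter,T/b,-0.57,1.36,1.21
diameter,D,-0.96,1.41,2.03
length_width_ratio,T/b,0.06,0.05,4.36
length_width_ratio,D,0.03,0.05,1.81
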