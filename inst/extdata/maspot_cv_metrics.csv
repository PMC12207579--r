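trait,r,sd_r,dispersion,h2_plot,h2_design,prediction_accuracy
dry_matter,0.61,0.005,1.15,0.29,0.31,1.09
yield,0.24,0.002,1.35,0.15,0.19,0.56
eye_depth,0.18,0.005,1.43,0.18,0.18,0.43
flesh_color,0.52,0.001,1.07,0.58,0.68,0.63
skin_finish,0.29,0.003,1.11,0.21,0.28,0.55
senescence,0.23,0.003,1.15,0.16,0.19,0.52
tubers_per_plant,0.33,0.002,1.16,0.28,0.33,0.57
length,0.49,0.002,1.07,0.47,0.54,0.67
diameter,0.33,0.002,1.18,0.34,0.38,0.53
length_width_ratio,0.42,0.002,1.16,0.45,0.49,0.60
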