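trait,min,max,mean,se,variance,cv,n_obs,n_rep
dry_matter,6.00,65.30,20.26,0.03,9.46,0.15,13481,3
yield,17.00,2136.00,616.71,2.10,37619.65,0.31,8562,2
eye_depth,1,5,2.68,0.01,0.65,0.30,4914,1
flesh_color,1,8,5.17,0.02,2.11,0.28,8551,2
skin_finish,1,5,2.66,0.01,0.62,0.30,8560,2
senescence,1,9,6.01,0.02,2.21,0.25,8570,2
tubers_per_plant,1.00,66.00,16.20,0.06,33.65,0.36,8524,2
length,27.67,136.80,65.63,0.12,119.57,0.17,8433,2
diameter,14.22,74.58,47.23,0.08,49.42,0.15,8433,2
length_width_ratio,1.13,3.76,1.44,0.00,0.04,0.14,8433,2
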