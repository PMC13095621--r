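plane,segment,n_male,mean_male,sd_male,n_female,mean_female,sd_female,ci_low_printed,ci_high_printed,t_printed,p_printed,d_printed
sagittal,L4 sup,19,1.32,0.70,14,1.35,0.41,-0.46,0.40,-0.15,0.89,-0.05
sagittal,L4 inf,19,1.77,0.56,14,2.06,0.43,-0.66,0.08,-1.61,0.11,-0.57
sagittal,L5 sup,19,1.33,0.71,14,1.25,0.44,-0.37,0.52,0.35,0.73,0.12
sagittal,L5 inf,19,1.89,0.73,14,1.98,0.69,-0.60,0.42,-0.35,0.73,-0.12
sagittal,S1 sup,19,0.63,0.65,14,0.44,0.25,-0.18,0.56,1.03,0.30,0.36
coronal,L4 sup,19,1.07,0.56,14,1.18,0.46,-0.47,0.28,-0.53,0.60,-0.19
coronal,L4 inf,19,3.16,0.99,14,3.43,1.15,-1.03,0.49,-0.72,0.48,-0.25
coronal,L5 sup,19,1.12,0.56,14,1.35,0.55,-0.56,0.22,-1.15,0.26,-0.32
coronal,L5 inf,19,3.20,0.82,14,3.28,0.82,-0.66,0.51,-0.26,0.80,-0.09
coronal,S1 sup,19,2.73,0.65,14,2.23,0.54,-0.09,1.10,1.74,0.09,0.61
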