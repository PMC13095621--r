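plane,segment,sex,n,uniform_concave,asymmetric_concave,flat_bottom,flat,p_exact_printed,cramers_v_printed
sagittal,L4 sup,male,19,4,5,2,8,0.14,0.41
sagittal,L4 sup,female,14,5,2,5,2,,
sagittal,L4 inf,male,19,7,6,4,2,0.61,0.28
sagittal,L4 inf,female,14,8,3,3,0,,
sagittal,L5 sup,male,19,1,11,1,6,0.83,0.19
sagittal,L5 sup,female,14,1,6,2,5,,
sagittal,L5 inf,male,19,4,11,1,3,0.94,0.10
sagittal,L5 inf,female,14,4,7,1,2,,
sagittal,S1 sup,male,19,0,2,1,16,1.00,0.17
sagittal,S1 sup,female,14,0,1,0,13,,
coronal,L4 sup,male,19,0,0,11,8,0.69,0.21
coronal,L4 sup,female,14,0,1,8,5,,
coronal,L4 inf,male,19,11,0,8,0,0.49,0.14
coronal,L4 inf,female,14,10,0,4,0,,
coronal,L5 sup,male,19,0,0,11,8,0.23,0.34
coronal,L5 sup,female,14,2,0,9,3,,
coronal,L5 inf,male,19,5,0,14,0,0.71,0.10
coronal,L5 inf,female,14,5,0,9,0,,
coronal,S1 sup,male,19,13,0,6,0,0.28,0.19
coronal,S1 sup,female,14,7,0,7,0,,
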