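plane,segment,uniform_concave,asymmetric_concave,flat_bottom,flat
sagittal,L4 sup,9,7,7,10
sagittal,L4 inf,15,9,7,2
sagittal,L5 sup,2,17,3,11
sagittal,L5 inf,8,18,2,5
sagittal,S1 sup,0,3,1,29
coronal,L4 sup,0,1,19,13
coronal,L4 inf,21,0,12,0
coronal,L5 sup,2,0,20,11
coronal,L5 inf,10,0,23,0
coronal,S1 sup,20,0,13,0
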