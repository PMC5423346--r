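patient,diagnosis,asl_intraop,asl_postop,anat_intraop,anat_postop,anat_postop_initial
1,RT,0,0,0,0,1
2,RT,1,1,1,1,1
3,RT,0,0,0,0,0
4,P,1,1,1,1,1
5,P(CTx),0,0,0,0,0
6,P,1,1,1,0,0
7,RT,1,0,1,0,0
8,P,1,1,1,1,1
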