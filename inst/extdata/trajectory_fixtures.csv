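parameter,sex,start_age,anchor_L,breakpoints,slopes
FEV1,F,4,0.95,13;20,0.234;0.099;-0.026
FEV1,M,4,1.00,16;23,0.271;0.108;-0.038
FVC,F,4,1.20,14;20,0.232;0.077;-0.026
FVC,M,4,1.30,15;23;42,0.326;0.156;-0.022;-0.036
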