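sex,age_years,median_bmi,sd_bmi
M,4,15.3,1.3
M,5,15.2,1.4
M,6,15.3,1.5
M,7,15.5,1.6
M,8,15.7,1.8
M,9,16.0,2.0
M,10,16.4,2.2
M,11,16.9,2.4
M,12,17.5,2.6
M,13,18.2,2.7
M,14,19.0,2.8
M,15,19.8,2.8
M,16,20.5,2.9
M,17,21.1,2.9
M,18,21.7,3.0
F,4,15.3,1.3
F,5,15.2,1.4
F,6,15.3,1.5
F,7,15.4,1.6
F,8,15.7,1.8
F,9,16.1,2.0
F,10,16.6,2.2
F,11,17.2,2.4
F,12,18.0,2.6
F,13,18.8,2.7
F,14,19.6,2.8
F,15,20.2,2.8
F,16,20.7,2.9
F,17,21.0,2.9
F,18,21.3,3.0
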