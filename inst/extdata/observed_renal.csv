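study,code,auc,auc_sd,half_life,half_life_sd,clearance,clearance_sd,fe,fe_sd,fe_cutoff
ohkawa,A1,72.9,14,1.55,0.3,8.2,1.5,90,4,24
ohkawa,A2,133,14,2.9,0.6,4.6,1.2,85,6,24
ohkawa,A3,192,32,3.9,0.9,2.9,1.0,76,11,24
ohkawa,A4,338,65,6.7,1.8,1.5,0.6,55,15,24
saito,B1,NA,NA,1.7,NA,NA,NA,90,NA,24
saito,B2,NA,NA,2.3,NA,NA,NA,88,NA,24
saito,B3,NA,NA,3.4,NA,NA,NA,78,NA,24
saito,B4,NA,NA,6.1,NA,NA,NA,70,NA,24
ackerman,C1,133,28,1.3,0.1,7.8,1.5,NA,NA,24
ackerman,C3,336,64,4.7,2,3.1,0.6,NA,NA,24
leroy,D1,127,15,1.6,0.1,7.8,0.8,84,4,24
leroy,D2,314,38,3.7,0.8,3.3,0.5,56,7,24
leroy,D3,773,119,9.3,1.1,1.3,0.1,45,13,24
leroy,D4,2313,414,25,4.1,0.4,0.0,0.0,NA,24
norrby,E1,118,38,1.5,0.4,9.4,3.3,NA,NA,24
norrby,E2,175,36,2.4,0.4,6.0,1.4,NA,NA,24
norrby,E3,228,24,3.4,0.3,4.4,0.5,NA,NA,24
welage,F1,152,37,1.7,0.2,7.0,1.7,78,23,24
welage,F2,336,39,3.6,0.5,3.0,0.3,80,15,24
welage,F3,582,86,6.3,2.4,1.8,0.3,74,11,24
van_dalen,G1,136,36,2.5,0.9,7.8,1.7,80,2,24
van_dalen,G2,190,6,3.7,1.1,5.3,0.2,88,5,24
van_dalen,G3,393,187,6.9,3.1,3.0,1.0,69,10,24
van_dalen,G4,1140,314,15.1,1.0,0.9,0.2,41,12,24
walstad,H1,232,34,2.8,0.5,4.4,0.7,94,8,24
walstad,H2,359,62,5.0,1.2,2.9,0.5,80,12,24
walstad,H3,279,54,8.6,1.7,1.9,0.4,58,5,24
lin,I1,410,13,3.3,1.1,5.7,NA,NA,NA,24
lin,I2,990,265,7.6,1.6,2.0,NA,NA,NA,24
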