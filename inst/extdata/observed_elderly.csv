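study,code,auc,auc_sd,half_life,half_life_sd,clearance,clearance_sd,fe,fe_sd,fe_cutoff
ljungberg_1984,A1,248,61,2.0,NA,8.06,NA,84,7,12
ljungberg_1984,A2,287,121,2.0,NA,6.97,NA,85,7.5,12
ljungberg_1984,A3,392,115,2.73,NA,5.1,NA,74,14,12
ljungberg_1984,A4,536,142,3.54,NA,5.73,NA,67,16,12
ljungberg_1978,B1,277,29,1.94,NA,7.22,0.8,87,10,12
ljungberg_1978,B2,418,52,2.63,NA,4.78,NA,72,8.6,12
naber,C1,271,NA,1.75,0.14,7.38,0.7,87,8.4,12
naber,C2,422,NA,2.9,0.5,4.74,1.0,57,18,12
lebel,D1,134,13,1.9,0.3,7.50,0.7,77,8.6,24
lebel,D2,224,79,1.9,0.7,4.99,2.0,76,13,24
deeter,E,409,62,3.7,2.0,4.89,0.80,NA,NA,12
higbee,G,463,209,3.9,1.3,4.9,1.4,71,3,12
shimada,F,287,93,3.7,1.1,NA,NA,71,3,12
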