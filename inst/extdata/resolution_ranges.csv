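scenario,G_mT_per_m,N,epsilon_um,SNR,lower_um,upper_um
perpendicular,300,1,1.0,10,3.4,7.5
perpendicular,300,1,1.0,20,2.8,8.0
perpendicular,300,1,1.0,50,2.2,8.2
perpendicular,300,1,0.5,10,4.2,6.2
perpendicular,300,1,0.5,20,3.2,7.1
perpendicular,300,1,0.5,50,2.5,8.0
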