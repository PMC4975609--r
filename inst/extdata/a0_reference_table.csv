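scenario,G_mT_per_m,SNR,N,a0_um
perpendicular,60,10,1,7.2
perpendicular,60,20,1,6.0
perpendicular,60,50,1,4.6
perpendicular,60,10,2,7.5
perpendicular,60,20,2,6.1
perpendicular,60,50,2,4.7
perpendicular,80,10,1,6.2
perpendicular,80,20,1,5.1
perpendicular,80,50,1,4.0
perpendicular,80,10,2,6.4
perpendicular,80,20,2,5.2
perpendicular,80,50,2,4.1
perpendicular,150,10,1,4.5
perpendicular,150,20,1,3.7
perpendicular,150,50,1,3.0
perpendicular,150,10,2,4.5
perpendicular,150,20,2,3.8
perpendicular,150,50,2,3.0
perpendicular,300,10,1,3.2
perpendicular,300,20,1,2.7
perpendicular,300,50,1,2.1
perpendicular,300,10,2,3.2
perpendicular,300,20,2,2.7
perpendicular,300,50,2,2.1
angle:10,60,10,1,7.8
angle:10,60,20,1,6.5
angle:10,60,50,1,5.0
angle:10,60,10,2,7.7
angle:10,60,20,2,6.3
angle:10,60,50,2,4.9
angle:10,80,10,1,6.9
angle:10,80,20,1,5.7
angle:10,80,50,1,4.5
angle:10,80,10,2,6.7
angle:10,80,20,2,5.4
angle:10,80,50,2,4.2
angle:10,150,10,1,5.3
angle:10,150,20,1,4.4
angle:10,150,50,1,3.5
angle:10,150,10,2,4.9
angle:10,150,20,2,4.1
angle:10,150,50,2,3.2
angle:10,300,10,1,4.3
angle:10,300,20,1,3.5
angle:10,300,50,1,2.8
angle:10,300,10,4,3.7
angle:10,300,20,4,3.1
angle:10,300,50,4,2.4
watson:16,60,10,1,7.7
watson:16,60,20,1,6.4
watson:16,60,50,1,5.0
watson:16,60,10,2,7.7
watson:16,60,20,2,6.3
watson:16,60,50,2,4.9
watson:16,80,10,1,6.8
watson:16,80,20,1,5.7
watson:16,80,50,1,4.4
watson:16,80,10,2,6.7
watson:16,80,20,2,5.4
watson:16,80,50,2,4.2
watson:16,150,10,1,5.2
watson:16,150,20,1,4.4
watson:16,150,50,1,3.4
watson:16,150,10,4,4.9
watson:16,150,20,4,4.1
watson:16,150,50,4,3.2
watson:16,300,10,1,4.1
watson:16,300,20,1,3.4
watson:16,300,50,1,2.7
watson:16,300,10,4,3.7
watson:16,300,20,4,3.0
watson:16,300,50,4,2.4
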