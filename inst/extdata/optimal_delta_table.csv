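scenario,G_mT_per_m,N,delta_ms
perpendicular,60,1,35
perpendicular,60,2,36
perpendicular,60,3,37
perpendicular,60,4,38
perpendicular,60,5,39
perpendicular,80,1,36
perpendicular,80,2,36
perpendicular,80,3,37
perpendicular,80,4,38
perpendicular,80,5,39
perpendicular,150,1,36
perpendicular,150,2,37
perpendicular,150,3,38
perpendicular,150,4,40
perpendicular,150,5,41
perpendicular,300,1,36
perpendicular,300,2,38
perpendicular,300,3,40
perpendicular,300,4,42
perpendicular,300,5,45
angle:10,60,1,21
angle:10,60,2,30
angle:10,60,3,33
angle:10,60,4,35
angle:10,60,5,37
angle:10,80,1,19
angle:10,80,2,28
angle:10,80,3,31
angle:10,80,4,35
angle:10,80,5,36
angle:10,150,1,13
angle:10,150,2,23
angle:10,150,3,26
angle:10,150,4,31
angle:10,150,5,33
angle:10,300,1,10
angle:10,300,2,18
angle:10,300,3,21
angle:10,300,4,27
angle:10,300,5,29
watson:16,60,1,23
watson:16,60,2,31
watson:16,60,3,33
watson:16,60,4,36
watson:16,60,5,37
watson:16,80,1,21
watson:16,80,2,29
watson:16,80,3,32
watson:16,80,4,35
watson:16,80,5,37
watson:16,150,1,16
watson:16,150,2,24
watson:16,150,3,27
watson:16,150,4,32
watson:16,150,5,34
watson:16,300,1,13
watson:16,300,2,20
watson:16,300,3,24
watson:16,300,4,29
watson:16,300,5,32
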