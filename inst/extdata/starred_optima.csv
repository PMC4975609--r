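figure,scenario,with_T2,a_um,G_mT_per_m,delta_ms,N
fig3,perpendicular,FALSE,2,300,60,1
fig3,perpendicular,FALSE,4,300,60,1
fig3,perpendicular,FALSE,6,187,60,1
fig3,perpendicular,FALSE,8,106,60,1
fig4,perpendicular,TRUE,2,300,36,1
fig4,perpendicular,TRUE,4,300,29,1
fig4,perpendicular,TRUE,6,300,17,1
fig4,perpendicular,TRUE,8,300,11,1
fig5,angle:1,TRUE,2,300,36,2
fig5,angle:1,TRUE,4,300,26,1
fig5,angle:1,TRUE,6,300,17,1
fig5,angle:6,TRUE,2,300,32,4
fig5,angle:6,TRUE,4,300,22,2
fig5,angle:6,TRUE,6,300,20,2
fig5,angle:10,TRUE,2,300,27,4
fig5,angle:10,TRUE,4,300,18,2
fig5,angle:10,TRUE,6,300,17,2
fig6,watson:16,TRUE,2,300,29,4
fig6,watson:16,TRUE,4,300,20,2
fig6,watson:16,TRUE,6,300,18,2
fig6,watson:8,TRUE,2,300,26,4
fig6,watson:8,TRUE,4,300,27,4
fig6,watson:8,TRUE,6,300,17,2
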