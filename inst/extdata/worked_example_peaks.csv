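well,x_um,y_um,z_um,a_wt,a_mut,a_hd1,a_hd2,a_ss,status
B1-A01-Z1,0,0,0,10000,1000,2000,2000,NA,ok
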