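"name","dv10_um","dv50_um","dv90_um","span","true_density_g_cm3"
"F1",2.24,4.42,8.84,1.492,1.05
"F2",2.43,4.67,8.51,1.304,1.06
"F3",2.2,4.03,7.1,1.217,1.17
"F4",1.87,5.13,12.21,2.016,1.23
"F5",2.26,3.94,6.63,1.11,1.03
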