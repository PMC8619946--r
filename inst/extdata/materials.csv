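"parameter","value","unit"
"E_s",4.1e+09,"Pa"
"E_p",1e+09,"Pa"
"v_s",0.35,"-"
"v_p",0.4,"-"
"W_A",0.039,"J/m^2"
"k_s",0.5,"-"
"f",1.7,"-"
"C_u",1,"-"
"mu",1.7894e-05,"Pa s"
"rho_air",1.225,"kg/m^3"
"e_n",0.8,"-"
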