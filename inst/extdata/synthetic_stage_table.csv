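"stage","label","cutoff_um","mass"
1,"device",NA,0.1
2,"IP",NA,0.139932
3,"S1",8.06,0
4,"S2",4.46,0.254313
5,"S3",2.82,0.229455
6,"S4",1.66,0.185067
7,"S5",0.94,0.074448
8,"S6",0.55,0.014913
9,"S7",0.34,0.001674
10,"MOC",NA,0.000198
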