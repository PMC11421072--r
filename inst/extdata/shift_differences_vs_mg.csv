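adp_conc_mM,mg_equiv,delta_delta_ppm
10,0,4.38
10,0.5,4.18
10,1,4.06
10,1.5,3.99
10,2,3.95
20,0,4.36
20,0.5,4.22
20,1,4.06
20,1.5,3.97
20,2,3.92
30,0,4.38
30,0.5,4.26
30,1,4.06
30,1.5,3.97
30,2,3.9
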