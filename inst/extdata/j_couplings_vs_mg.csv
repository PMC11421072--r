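adp_conc_mM,mg_equiv,j_ab_hz
10,0,22.6
10,0.5,19.5
10,1,17.7
10,1.5,17.3
10,2,17.2
20,0,22.5
20,0.5,19.4
20,1,17.6
20,1.5,17.1
20,2,16.9
30,0,22.5
30,0.5,19.4
30,1,17.5
30,1.5,17.0
30,2,16.7
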