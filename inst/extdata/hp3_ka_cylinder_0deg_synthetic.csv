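energy_keV,value
10,0.280
15,0.700
20,1.020
25,1.230
30,1.380
35,1.490
40,1.550
45,1.600
50,1.630
60,1.661
70,1.670
80,1.655
100,1.600
125,1.540
150,1.490
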