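"voltage_V","current_A"
-0.06,-1.46624294715462e-12
-0.048,-9.29007043374258e-13
-0.036,-1.02354235318675e-12
-0.024,-4.83064962286972e-13
-0.012,-1.80455634805919e-13
0,3.5218988626881e-13
0.012,4.59323356687791e-13
0.024,5.13552505573736e-13
0.036,1.09616768685381e-12
0.048,1.02776779061182e-12
0.06,1.52636642966209e-12
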