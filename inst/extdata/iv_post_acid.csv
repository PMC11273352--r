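"voltage_V","current_A"
-0.06,-7.9283631294541e-12
-0.048,-6.46989658796932e-12
-0.036,-5.83406297213615e-12
-0.024,-3.55592093812203e-12
-0.012,-2.50216568865217e-12
0,-1.23631878115818e-12
0.012,-5.04558347360574e-14
0.024,1.03400932652236e-12
0.036,2.3999857022576e-12
0.048,4.08332011530484e-12
0.06,5.2228720842571e-12
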