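"xi","dG_kJ_per_mol","flux_ions_per_s"
0.1,0,0
0.12,1.51703703703704e-05,0
0.14,0.000242725925925926,0
0.16,0.0012288,0
0.18,0.00388361481481481,0
0.2,0.00948148148148148,0
0.22,0.0196608,0
0.24,0.0364240592592593,0
0.26,0.062137837037037,0
0.28,0.0995328,0
0.3,0.151703703703704,0
0.32,0.222109392592593,0
0.34,0.3145728,0
0.36,0.433280948148148,0
0.38,0.582784948148148,0
0.4,0.768000000000001,0
0.42,0.994205392592593,0
0.44,1.2670445037037,0
0.46,1.5925248,0
0.48,1.97701783703704,0
0.5,2.42725925925926,0
0.52,2.9503488,0
0.54,3.55375028148148,0
0.56,4.24529161481482,0
0.58,5.0331648,0
0.6,5.92592592592592,0
0.62,6.93249517037037,179862.099620916
0.64,8.0621568,344451.956662112
0.66,9.32455917037037,649691.691286641
0.68,10.7297147259259,1192029.22022117
0.7,12.288,2086085.27326045
0.72,14.0101556148148,3392436.31234183
0.74,15.9072862814815,5e+06
0.76,17.9908608,6607563.68765817
0.78,20.2727120592593,7913914.72673955
0.8,22.765037037037,8807970.77977883
0.82,25.4803968,9350308.30871336
0.84,28.4317165037037,9655548.04333789
0.86,31.6322853925926,9820137.90037908
0.88,35.0957568,9906840.40654933
0.9,38.8361481481481,9951952.4711284
0.92,42.8678409481482,9975273.76843365
0.94,47.2055808,9987289.83736919
0.96,51.8644773925926,9993470.34662447
0.98,56.8600045037037,9996646.49869534
1,62.208,9998277.97402881
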