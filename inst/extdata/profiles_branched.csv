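"xi","dG_kJ_per_mol","flux_ions_per_s"
0.1,0,0
0.12,0.0187404733892758,0
0.14,0.0497389618307845,0
0.16,0.101182654572309,0
0.18,0.186288462242295,0
0.2,0.325850597251086,0
0.22,0.551688212497729,0
0.24,0.910506994416043,0
0.26,1.46618413830543,0
0.28,2.29557112615667,0
0.3,3.46969795146053,0
0.32,5.01476247587663,0
0.34,6.86564702270238,0
0.36,8.85325122803468,0
0.38,10.761176367453,0
0.4,12.4210502548321,0
0.42,13.7692115690249,0
0.44,14.8340427050242,0
0.46,15.6894863674321,0
0.48,16.4160349271282,0
0.5,17.0819346460786,0
0.52,17.7389884551614,0
0.54,18.4248409294981,0
0.56,19.1668398814989,0
0.58,19.98548399957,0
0.6,20.8969704285148,0
0.62,21.9149199667373,179862.099620916
0.64,23.0514925104597,344451.956662112
0.66,24.3180896631969,649691.691286641
0.68,25.7257906247309,1192029.22022117
0.7,27.2856201858716,2086085.27326045
0.72,29.008712612811,3392436.31234183
0.74,30.9064115416655,5e+06
0.76,32.990330749563,6607563.68765817
0.78,35.2723910812024,7913914.72673955
0.8,37.764842870623,8807970.77977883
0.82,40.480279549778,9350308.30871336
0.84,43.431645905894,9655548.04333789
0.86,46.6322430910424,9820137.90037908
0.88,50.0957316610506,9906840.40654933
0.9,53.8361334188615,9951952.4711284
0.92,57.8678325326481,9975273.76843365
0.94,62.2055762140077,9987289.83736919
0.96,66.8644751293151,9993470.34662447
0.98,71.8600036492243,9996646.49869534
1,77.208,9998277.97402881
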