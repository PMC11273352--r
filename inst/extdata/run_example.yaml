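# Acid-on-bottom run: pH 4.1/7.3, 55 um aperture, room temperature
radius_um: 55
i_proton_A: -7.6e-12
U_bias_V: -0.06
i_zero_bias_A: 1.53e-12
duration_s: 3600
iv_files:
  - iv_pre_acid.csv
  - iv_post_acid.csv
profile_files:
  - profiles_unsaturated.csv
  - profiles_branched.csv
conditions:
  pH_bottom: 4.1
  pH_top: 7.3
  cl_bottom: 0.061
  cl_top: 0.050
capacitor:
  eps: 2.1
  d_nm: 4
calibration:
  chi3_prime: 1
  intensity_scale: 20000
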