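# Spectral absorption coefficients for the clear-sky marine atmosphere model.
# a_ozone: ozone (Chappuis band), per atm-cm; a_oxygen: per air mass;
# a_water: water vapour, per cm of precipitable water. Coarse tabulation
# interpolated to 1 nm at load time; visible-band values only.
wavelength_nm,a_ozone,a_oxygen,a_water
350,0.000,0,0
400,0.000,0,0
440,0.003,0,0
450,0.004,0,0
460,0.006,0,0
470,0.009,0,0
480,0.014,0,0
490,0.021,0,0
500,0.030,0,0
510,0.040,0,0
520,0.048,0,0
530,0.060,0,0
540,0.075,0,0
550,0.085,0,0
560,0.103,0,0
570,0.118,0,0
580,0.125,0,0.011
590,0.120,0,0.075
600,0.125,0,0.014
610,0.120,0,0.003
620,0.105,0,0
630,0.090,0,0
640,0.079,0,0
650,0.067,0,0
660,0.055,0,0
670,0.045,0,0
680,0.035,0.007,0
685,0.031,0.300,0.005
690,0.027,0.200,0.016
695,0.025,0.010,0.012
700,0.023,0.000,0.020
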