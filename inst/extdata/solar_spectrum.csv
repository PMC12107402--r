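# Top-of-atmosphere solar spectral irradiance, W m-2 nm-1.
# Smoothed 10 nm representation of the standard extraterrestrial reference
# spectrum (Neckel & Labs-type lookup); interpolated to 1 nm at load time.
wavelength_nm,irradiance
350,1.000
360,1.050
370,1.150
380,1.100
390,1.250
400,1.700
410,1.750
420,1.720
430,1.650
440,1.830
450,2.040
460,2.070
470,2.040
480,2.070
490,1.950
500,1.930
510,1.920
520,1.850
530,1.920
540,1.870
550,1.870
560,1.830
570,1.810
580,1.820
590,1.780
600,1.750
610,1.720
620,1.690
630,1.650
640,1.610
650,1.570
660,1.540
670,1.510
680,1.480
690,1.450
700,1.420
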