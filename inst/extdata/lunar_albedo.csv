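# Spectral lunar albedo (unitless), increasing with wavelength as in
# telescopic lunar photometry (Velikodsky-type); interpolated to 1 nm.
wavelength_nm,albedo
350,0.072
400,0.090
450,0.105
500,0.118
550,0.130
600,0.142
650,0.154
700,0.165
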