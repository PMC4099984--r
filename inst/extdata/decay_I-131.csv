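# I-131 emission inventory (simplified line list).
# Transcribed/rounded from a standard ENSDF-derived decay-data compilation;
# lines with yield < ~0.05% omitted at transcription. Energies in MeV,
# yields per decay. Beta branches give the endpoint energy; z_daughter is
# the daughter atomic number used in the Fermi shape. Conversion-electron
# rows are per subshell line (tag = subshell+transition); Auger rows are per
# group component (tag = group).
type,particle,origin,energy_MeV,yield,z_daughter,tag
half_life,,,192.608,,,
line,photon,gamma,0.080185,0.0262,,g80
line,photon,gamma,0.177214,0.00269,,g177
line,photon,gamma,0.284305,0.0612,,g284
line,photon,gamma,0.325789,0.00274,,g326
line,photon,gamma,0.364489,0.8150,,g364
line,photon,gamma,0.502991,0.00359,,g503
line,photon,gamma,0.636989,0.0716,,g637
line,photon,gamma,0.722911,0.0177,,g723
line,photon,xray,0.029461,0.0390,,XeKa
line,photon,xray,0.033600,0.0090,,XeKb
line,photon,xray,0.004100,0.0080,,XeL
beta,,beta-minus,0.247900,0.0212,54,b248
beta,,beta-minus,0.333800,0.0723,54,b334
beta,,beta-minus,0.606300,0.8960,54,b606
beta,,beta-minus,0.806900,0.0040,54,b807
line,electron,conversion,0.045622,0.0353,,K80
line,electron,conversion,0.074731,0.00457,,L80
line,electron,conversion,0.249760,0.00250,,K284
line,electron,conversion,0.329760,0.0155,,K364
line,electron,conversion,0.358570,0.00175,,L364
line,electron,conversion,0.359070,0.00028,,L364
line,electron,conversion,0.359770,0.00043,,L364
line,electron,auger,0.022700,0.0036,,K-auger
line,electron,auger,0.026600,0.0014,,K-auger
line,electron,auger,0.030400,0.0004,,K-auger
line,electron,auger,0.003100,0.0510,,L-auger
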