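# I-123 emission inventory (simplified line list). Electron-capture decay to
# Te-123; no beta branches. Transcribed/rounded from a standard
# ENSDF-derived decay-data compilation. Energies MeV, yields per decay.
type,particle,origin,energy_MeV,yield,z_daughter,tag
half_life,,,13.2235,,,
line,photon,gamma,0.158970,0.8330,,g159
line,photon,gamma,0.440020,0.00428,,g440
line,photon,gamma,0.505330,0.00316,,g505
line,photon,gamma,0.528960,0.0139,,g529
line,photon,gamma,0.538540,0.00382,,g539
line,photon,gamma,0.783590,0.00059,,g784
line,photon,xray,0.027400,0.7130,,TeKa
line,photon,xray,0.031000,0.1600,,TeKb
line,photon,xray,0.004000,0.0900,,TeL
line,electron,conversion,0.127180,0.1360,,K159
line,electron,conversion,0.154030,0.0143,,L159
line,electron,conversion,0.154550,0.0018,,L159
line,electron,conversion,0.155090,0.0010,,L159
line,electron,conversion,0.158300,0.0044,,M159
line,electron,auger,0.022500,0.0710,,K-auger
line,electron,auger,0.026400,0.0180,,K-auger
line,electron,auger,0.030200,0.0050,,K-auger
line,electron,auger,0.003000,0.9400,,L-auger
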