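# Tc-99m emission inventory (simplified line list). Isomeric transition; no
# beta branches. Transcribed/rounded from a standard ENSDF-derived
# decay-data compilation. Energies MeV, yields per decay.
type,particle,origin,energy_MeV,yield,z_daughter,tag
half_life,,,6.0067,,,
line,photon,gamma,0.140511,0.8850,,g141
line,photon,gamma,0.142630,0.00023,,g143
line,photon,xray,0.018300,0.0406,,TcKa
line,photon,xray,0.020600,0.0081,,TcKb
line,electron,conversion,0.119467,0.0879,,K141
line,electron,conversion,0.137468,0.0107,,L141
line,electron,conversion,0.140025,0.0019,,M141
line,electron,conversion,0.121590,0.00067,,K143
line,electron,auger,0.015400,0.0210,,K-auger
line,electron,auger,0.002200,0.9000,,L-auger
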