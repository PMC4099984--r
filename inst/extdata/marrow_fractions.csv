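# Active (red) marrow mass fractions by skeletal site, adult-female style
# distribution used to aggregate site doses into the active-marrow dose.
# Fractions sum to 1; the table is configurable.
site,fraction
cranium,0.076
mandible,0.008
arm bones,0.023
ribs,0.161
sternum,0.031
cervical spine,0.039
thoracic spine,0.163
lumbar spine,0.123
sacrum,0.099
os coxae,0.175
leg bones,0.102
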