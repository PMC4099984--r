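# Editable rate-constant bundle for the iodide-in-pregnancy compartmental
# model. Rates are per day; f_* are dimensionless split fractions. These are
# package defaults (the published pregnancy model does not print its rate
# constants): conventional iodide kinetics tuned only to reproduce the
# qualitative maximum-thyroid-uptake trends. Edit and pass to
# build_iodide_pregnancy_model(constants = read_constants_bundle(path)).
lambda_blood: 4.0
f_urine: 0.60
f_salivary: 0.10
f_gastric: 0.15
f_placenta: 0.15
k_salivary: 5.0
k_stomach: 4.0
k_si: 3.5
f_si_absorbed: 0.99
k_kidney: 160.0
k_thyroid_release: 0.013863
k_metabolism: 0.057762
f_met_liver: 0.5
f_met_blood: 0.4
f_met_feces: 0.1
k_liver_release: 0.05
k_fetal_thyroid: 1.35
k_fetal_back: 9.0
k_fetal_thy_release: 0.013863
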