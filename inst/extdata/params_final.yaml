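# Typical parameters of the final population model (the package defaults),
# in the configuration format accepted by counterreg_run()'s `params` key
# and by hormone_params(). Units: glucose mmol/L, insulin uU/mL, glucagon
# and ACTH pmol/L, cortisol nmol/L, rates 1/min, t_half min; CVs and
# residual errors as fractions.
gn0: 8.35
kout_g: 0.0612
frac: 0.750
ic50_g: 2.91
gamma_g: 5.26
ic50_i: 5.51
theta_gir_i: -0.157
sigma_g: 0.338
acth0: 2.94
kout_a: 0.0709
t_half: 8.68
imax_a: 0.941
ic50_a: 2.85
gamma_a: 20.9
theta_gir_a: -0.0155
sigma_a: 0.381
cort0: 207
kout_c: 0.0608
emax_c: 41.8
ec50_c: 6.90
gamma_c: 1.29
sigma_c: 0.293
f_add: 2.01
gir_ref: 8.13
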