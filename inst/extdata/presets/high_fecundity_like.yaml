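# Fertility-selected line: very large litters (mean ~21.7, max 30),
# smaller slope variances, higher residual variance.
n_generations: 40
pairs_per_generation: 55
truth:
  sigma_t2: 0.949
  sigma_s2: 0.220
  sigma_ts: 0.406
  sigma_e2: 4.408
n_max: 30
ls_mean: 21.74
ls_sd: 3.38
age_mean: 90
age_sd: 25
generation_effect_sd: 1.0
beta_age: [0.5, -0.3]
beta0: 55.0
intercept: 0.0
sire_double_fraction: 0.0
avoid_full_sibs: true
mode: rrm_exact
seed: 1
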