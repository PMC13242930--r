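# Growth-selected line: litter sizes around 11 (max 22), heavy litters,
# large sire variance, negative dam-sire covariance, some sires mated twice.
n_generations: 40
pairs_per_generation: 50
truth:
  sigma_t2: 7.433
  sigma_s2: 4.976
  sigma_ts: -2.181
  sigma_e2: 3.925
n_max: 22
ls_mean: 11.06
ls_sd: 3.66
age_mean: 90
age_sd: 25
generation_effect_sd: 1.5
beta_age: [0.5, -0.3]
beta0: 57.0
intercept: 0.0
sire_double_fraction: 0.12
avoid_full_sibs: true
mode: rrm_exact
seed: 1
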