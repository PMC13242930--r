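# Unselected control line: ~40 generations x 125 pairs, litter sizes
# around 11.6 (max 22), moderate dam slope variance, small sire variance.
n_generations: 40
pairs_per_generation: 125
truth:
  sigma_t2: 2.631
  sigma_s2: 0.137
  sigma_ts: 0.596
  sigma_e2: 2.056
n_max: 22
ls_mean: 11.61
ls_sd: 2.98
age_mean: 90
age_sd: 25
generation_effect_sd: 1.0
beta_age: [0.5, -0.3]
beta0: 39.0
intercept: 0.0
sire_double_fraction: 0.0
avoid_full_sibs: true
mode: rrm_exact
seed: 1
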