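test_that("RLRT arithmetic, clamping and guards work", {
  same <- rlrt_from_loglik(-100, -100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(small <- rlrt_from_loglik(-100.00001, -100), "clamped")
  expect_equal(small$statistic, 0)
  expect_error(rlrt_from_loglik(-105, -100), "refit")
  t1 <- rlrt_from_loglik(-4961.12, -4969.80)
  expect_equal(t1$statistic, 17.36)
  expect_true(t1$significant)
  expect_output(print(t1), "RLRT")
})

test_that("rlrt_sire checks model structure and data identity", {
  s <- small_sim(seed = 17, ngen = 4, pairs = 18)
  full <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                  control = fast_ctl())
  red <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                 include_sire = FALSE, control = fast_ctl())
  tst <- rlrt_sire(full, red)
  expect_gte(tst$statistic, 0)
  expect_equal(tst$df, 2)
  expect_error(rlrt_sire(red, full), "sire block")
  other <- s$sim$litters
  other$litter_weight_g <- other$litter_weight_g + 1
  red2 <- rrm_fit(other, s$sim$pedigree, n_max = s$cfg$n_max,
                  include_sire = FALSE, control = fast_ctl())
  expect_error(rlrt_sire(full, red2), "identical data")
  # boundary mixture is more liberal than the plain 2-df reference
  mix <- rlrt_sire(full, red, boundary_mixture = TRUE)
  expect_lte(mix$p_value, tst$p_value + 1e-12)
})

test_that("the RLRT is invariant to fixed-effect reparameterization", {
  s <- small_sim(seed = 23, ngen = 4, pairs = 20)
  lit <- s$sim$litters
  ctl <- fast_ctl()
  f1 <- rrm_fit(lit, s$sim$pedigree, n_max = s$cfg$n_max, control = ctl)
  r1 <- rrm_fit(lit, s$sim$pedigree, n_max = s$cfg$n_max,
                include_sire = FALSE, control = ctl)
  # relabel generations in reverse order: different reference level
  lit2 <- lit
  lit2$generation <- max(lit$generation) + 1 - lit$generation
  f2 <- rrm_fit(lit2, s$sim$pedigree, n_max = s$cfg$n_max, control = ctl)
  r2 <- rrm_fit(lit2, s$sim$pedigree, n_max = s$cfg$n_max,
                include_sire = FALSE, control = ctl)
  t1 <- rlrt_sire(f1, r1)
  t2 <- rlrt_sire(f2, r2)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-4)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-4)
})

test_that("baseline variants fit and differ as designed", {
  s <- small_sim(seed = 19, ngen = 5, pairs = 25)
  lit <- s$sim$litters
  ped <- s$sim$pedigree
  ctl <- fast_ctl()
  frrm <- rrm_fit(lit, ped, variant = "RRM", n_max = s$cfg$n_max,
                  control = ctl)
  ftlw <- rrm_fit(lit, ped, variant = "TLW", include_sire = FALSE,
                  control = ctl)
  expect_true(frrm$converged && ftlw$converged)
  expect_false(isTRUE(all.equal(frrm$loglik, ftlw$loglik)))
  fabw <- rrm_fit(lit, ped, variant = "ABW", control = ctl)
  expect_equal(fabw$design$y, lit$litter_weight_g / lit$litter_size)
  expect_true(fabw$include_sire)  # dam + sire intercepts for the sire test
  flwa <- rrm_fit(lit, ped, variant = "LWA", include_sire = FALSE,
                  control = ctl)
  expect_true("ls_n" %in% flwa$design$fixed_labels)
  expect_false("ls_n" %in% ftlw$design$fixed_labels)
})

test_that("the sire test has power against a control-line-scale sire effect", {
  ctl <- fast_ctl(reltol = 1e-8)
  n_rep <- 15
  rej <- logical(n_rep)
  stat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_generations = 12, pairs_per_generation = 80,
                      seed = 700 + r)  # truth sigma_s2 = 0.14, sigma_ts = 0.6
    sim <- simulate_dataset(cfg)
    full <- rrm_fit(sim$litters, sim$pedigree, n_max = 22, control = ctl)
    red <- rrm_fit(sim$litters, sim$pedigree, n_max = 22,
                   include_sire = FALSE, control = ctl)
    tt <- suppressWarnings(rlrt_sire(full, red))
    rej[r] <- tt$significant
    stat[r] <- tt$statistic
  }
  # rejection well above the nominal 5% size, statistics above the null mean
  expect_gt(mean(rej), 0.2)
  expect_gt(mean(stat), 2)
})

test_that("bivariate model recovers the dam LW-LS genetic correlation", {
  G3 <- matrix(c(2.6, 0.6, -1.2,
                 0.6, 0.5, -0.1,
                 -1.2, -0.1, 1.5), 3, 3)
  R2 <- matrix(c(2.1, 0.3, 0.3, 6), 2, 2)
  cfg <- sim_config(n_generations = 10, pairs_per_generation = 60, seed = 5,
                    mode = "bivariate", truth_biv = list(G3 = G3, R2 = R2))
  sim <- simulate_dataset(cfg)
  bf <- fit_bivariate_lw_ls(sim$litters, sim$pedigree, n_max = cfg$n_max)
  expect_true(bf$converged)
  r_true <- G3[1, 3] / sqrt(G3[1, 1] * G3[3, 3])
  r_hat <- bf$correlations[["r_dam_t1_ls"]]
  expect_lt(abs(r_hat - r_true), 0.35)
  expect_lt(r_hat, 0)  # the sign is identified
  # the residual LW-LS covariance is estimated, not assumed zero
  expect_true(is.finite(bf$R2[1, 2]))
  expect_output(print(bf), "Bivariate")
})

test_that("degenerate bivariate input is rejected", {
  s <- small_sim(seed = 29, ngen = 3, pairs = 10)
  lit <- s$sim$litters
  lit$litter_weight_g <- as.numeric(lit$litter_size)
  expect_error(fit_bivariate_lw_ls(lit, s$sim$pedigree), "degenerate")
})
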