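test_that("the same configuration reproduces the identical dataset", {
  cfg <- sim_config(n_generations = 3, pairs_per_generation = 12, seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$litters, b$litters)
  expect_identical(as.data.frame(a$pedigree), as.data.frame(b$pedigree))
  expect_identical(a$effects, b$effects)
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(simulate_dataset(cfg2)$litters, a$litters))
})

test_that("pedigree bookkeeping is consistent", {
  cfg <- sim_config(n_generations = 2, pairs_per_generation = 10, seed = 1)
  sk <- simulate_pedigree(cfg)
  expect_equal(nrow(sk$skeleton), 20)          # one litter per pair
  expect_equal(sk$ped$n, 2 * 10 * 2)           # founders + cohort-1 breeders
  expect_true(all(sk$skeleton$dam %in% sk$ped$id))
  expect_true(all(sk$skeleton$sire %in% sk$ped$id))
  # litters reference parents from the previous generation only
  gen_of <- function(id) sk$ped$generation[match(id, sk$ped$id)]
  expect_true(all(sk$skeleton$generation - gen_of(sk$skeleton$dam) == 1))
})

test_that("sib avoidance keeps shared-parent matings out", {
  cfg <- sim_config(n_generations = 8, pairs_per_generation = 15, seed = 6,
                    avoid_full_sibs = TRUE)
  sk <- simulate_pedigree(cfg)
  ped <- sk$ped
  di <- match(sk$skeleton$dam, ped$id)
  si <- match(sk$skeleton$sire, ped$id)
  later <- sk$skeleton$generation > 1
  shares <- (ped$sire[di] == ped$sire[si]) | (ped$dam[di] == ped$dam[si]) |
    (ped$sire[di] == ped$dam[si]) | (ped$dam[di] == ped$sire[si])
  expect_false(any(shares[later]))
})

test_that("double-mated sires appear at the requested rate", {
  cfg <- sim_config(n_generations = 6, pairs_per_generation = 50, seed = 2,
                    sire_double_fraction = 0.2)
  sk <- simulate_pedigree(cfg)
  per_sire <- table(sk$skeleton$sire)
  expect_true(any(per_sire == 2))
  expect_equal(mean(per_sire > 1), 0.2 / 0.8, tolerance = 0.1)
})

test_that("founder effects match the base-population covariance", {
  ped <- pedigree(sprintf("F%05d", 1:10000), rep(NA, 10000), rep(NA, 10000))
  G <- matrix(c(2.6, 0.6, 0.6, 0.9), 2, 2)
  u <- simulate_breeding_values(ped, G, seed = 9)
  emp <- stats::cov(u)
  # 3 x Monte Carlo SE bounds for variances and the covariance
  tol <- 3 * sqrt(2 / 10000) * max(diag(G))
  expect_true(all(abs(emp - G) < tol))
})

test_that("sire slope variance is a quarter of the direct variance", {
  s <- small_sim(seed = 13, ngen = 4, pairs = 40)
  eff <- s$sim$effects
  expect_equal(stats::var(eff$a_s), 0.25 * stats::var(eff$b))
  # slope effects reconstruct from (m, b) exactly
  sl <- slope_effects(eff$m, eff$b)
  expect_equal(sl$a_d, eff$a_d)
})

test_that("inbreeding shrinks the Mendelian sampling variance", {
  # selfing-free but heavily drifting population: descendants should have
  # conditional variance below the founder variance
  cfg <- sim_config(n_generations = 12, pairs_per_generation = 6, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_gt(mean(inbreeding(sim$pedigree)[sim$pedigree$generation == 11]),
            0.05)
})

test_that("litter residual variance is flat in rrm_exact, grows pup-level", {
  base <- list(n_generations = 1, pairs_per_generation = 4000, seed = 5,
               truth = list(sigma_t2 = 0, sigma_s2 = 0, sigma_ts = 0,
                            sigma_e2 = 2.1),
               generation_effect_sd = 0, beta_age = c(0, 0), ls_sd = 6)
  resid_var_by_n <- function(mode) {
    cfg <- do.call(sim_config, c(base, list(mode = mode)))
    sim <- simulate_dataset(cfg)
    lit <- sim$litters
    e <- lit$litter_weight_g - cfg$beta0 * lit$litter_size / cfg$n_max
    lo <- lit$litter_size <= 8
    hi <- lit$litter_size >= 15
    c(stats::var(e[lo]), stats::var(e[hi]))
  }
  vr <- resid_var_by_n("rrm_exact")
  expect_equal(vr[2] / vr[1], 1, tolerance = 0.2)
  vp <- resid_var_by_n("pup_level")
  expect_gt(vp[2] / vp[1], 1.6)
})

test_that("scenario presets load and mirror their line statistics", {
  cfg <- sim_preset("fztdu_like")
  expect_equal(cfg$truth$sigma_t2, 2.631)
  expect_equal(cfg$n_max, 22)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$litters), 5000)
  expect_lt(abs(mean(sim$litters$litter_size) - 11.61), 0.5)
  expect_lt(abs(mean(sim$litters$litter_weight_g) - 20.65), 3)
  cfg2 <- sim_preset("du6_like", n_generations = 2)
  expect_equal(cfg2$n_generations, 2)
  expect_gt(cfg2$sire_double_fraction, 0)
})

test_that("population collapse is reported", {
  cfg <- sim_config(n_generations = 6, pairs_per_generation = 2, seed = 1,
                    avoid_full_sibs = TRUE)
  expect_error(simulate_pedigree(cfg), "collapse")
})
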