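test_that("sparse MME likelihood equals the dense variance-matrix oracle", {
  for (seed in 1:4) {
    ped <- random_pedigree(80, seed = seed)
    lit <- random_litters(ped, 50, seed = seed + 10)
    dm <- build_design(lit, ped, variant = "RRM", n_max = 16)
    ainv <- a_inverse(ped)
    A <- a_matrix(ped)
    set.seed(seed)
    L <- matrix(c(rlnorm(1), rnorm(1), 0, rlnorm(1)), 2, 2)
    G <- L %*% t(L) + diag(0.05, 2)
    se2 <- rlnorm(1, 0.5)
    expect_equal(reml_loglik(dm, G, se2, ainv),
                 reml_loglik_direct(dm, G, se2, A), tolerance = 1e-7)
    # dam-only model too
    dm1 <- build_design(lit, ped, variant = "RRM", n_max = 16,
                        include_sire = FALSE)
    expect_equal(reml_loglik(dm1, G[1, 1, drop = FALSE], se2, ainv),
                 reml_loglik_direct(dm1, G[1, 1, drop = FALSE], se2, A),
                 tolerance = 1e-7)
  }
})

test_that("mixed-model equations match a hand-assembled tiny system", {
  ped <- pedigree(c("d1", "s1"), c(NA, NA), c(NA, NA))
  lit <- data.frame(litter_id = "L1", dam = "d1", sire = "s1",
                    generation = 1, mating_age_days = 100,
                    litter_size = 11, litter_weight_g = 20)
  dm <- build_design(lit, ped, variant = "RRM", n_max = 22,
                     age_poly_order = 0)
  ainv <- a_inverse(ped)
  ws <- rrmlw:::.mme_prep(dm, ainv)
  st <- 2.5; ss <- 0.8; se2 <- 1.7
  Ginv <- solve(diag(c(st, ss)) / se2)
  xv <- numeric(ws$nnz)
  xv[ws$pos_w] <- ws$wx
  for (s in seq_along(ws$pos_b)) {
    kl <- ws$blk[[s]]
    xv[ws$pos_b[[s]]] <- xv[ws$pos_b[[s]]] + Ginv[kl[1], kl[2]] * ws$bx[[s]]
  }
  C <- ws$Tm; C@x <- xv
  x <- 0.5  # 11 / 22
  # columns: intercept, dam d1, dam s1, sire d1, sire s1 (founders: A = I)
  i_d <- 1 + match("d1", ped$id)
  i_s <- 3 + match("s1", ped$id)
  Cm <- as.matrix(C)
  expect_equal(Cm[1, 1], 1)
  expect_equal(Cm[1, i_d], x)
  expect_equal(Cm[i_d, i_d], x^2 + se2 / st)
  expect_equal(Cm[i_s, i_s], x^2 + se2 / ss)
  expect_equal(Cm[i_d, i_s], x^2)
  # off-block between the two animals' dam effects: founders are unrelated,
  # so only the data cross-product remains (zero: different animals)
  expect_equal(Cm[2, 3], 0)
})

test_that("vanishing genetic variance recovers the OLS restricted likelihood", {
  ped <- random_pedigree(40, seed = 5)
  lit <- random_litters(ped, 60, seed = 5)
  dm <- build_design(lit, ped, variant = "RRM", n_max = 16)
  X <- as.matrix(dm$X)
  y <- dm$y
  n <- length(y); p <- ncol(X)
  se2 <- 3.7
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  ols <- -0.5 * ((n - p) * log(se2) + determinant(crossprod(X))$modulus +
                   rss / se2 + (n - p) * log(2 * pi))
  lim <- reml_loglik_direct(dm, diag(1e-10, 2), se2, a_matrix(ped))
  expect_equal(lim, ols, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("EM-REML and the profiled search find the same optimum", {
  s <- small_sim(seed = 21, ngen = 4, pairs = 20,
                 truth = list(sigma_t2 = 3, sigma_s2 = 1, sigma_ts = 0.5,
                              sigma_e2 = 1.5))
  ainv <- a_inverse(s$sim$pedigree)
  # dam-only model: well-conditioned, both algorithms agree tightly
  dm1 <- build_design(s$sim$litters, s$sim$pedigree, variant = "RRM",
                      n_max = s$cfg$n_max, include_sire = FALSE)
  fit1 <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                  include_sire = FALSE, control = fast_ctl())
  em1 <- reml_fit_em(dm1, ainv, maxit = 5000, tol = 1e-13)
  expect_lt(abs(em1$loglik - fit1$loglik), 1e-4)
  expect_equal(em1$G[1, 1], fit1$varcomp$sigma_t2, tolerance = 0.01)
  expect_equal(em1$sigma_e2, fit1$varcomp$sigma_e2, tolerance = 0.01)
  # two-block model: EM climbs monotonically towards the same optimum and
  # never overtakes the direct maximizer
  dm2 <- build_design(s$sim$litters, s$sim$pedigree, variant = "RRM",
                      n_max = s$cfg$n_max)
  fit2 <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                  control = fast_ctl())
  em_a <- reml_fit_em(dm2, ainv, maxit = 150, tol = 0)
  em_b <- reml_fit_em(dm2, ainv, maxit = 1500, tol = 0)
  expect_gt(em_b$loglik, em_a$loglik)        # monotone ascent
  expect_lte(em_b$loglik, fit2$loglik + 1e-4)  # no point above the optimum
  expect_lt(fit2$loglik - em_b$loglik, 0.05)   # and EM is closing in
})

test_that("the returned optimum is no worse than the default start", {
  s <- small_sim(seed = 8)
  fit <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                 control = fast_ctl())
  vy <- stats::var(s$sim$litters$litter_weight_g)
  G0 <- matrix(c(0.4, 0, 0, 0.1), 2, 2) * vy
  dm <- build_design(s$sim$litters, s$sim$pedigree, variant = "RRM",
                     n_max = s$cfg$n_max)
  l0 <- reml_loglik(dm, G0, 0.5 * vy, a_inverse(s$sim$pedigree))
  expect_gte(fit$loglik, l0)
  expect_true(fit$converged)
})

test_that("the full model never falls below the dam-only model", {
  for (seed in c(3, 14)) {
    s <- small_sim(seed = seed, ngen = 4, pairs = 20)
    full <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                    control = fast_ctl())
    red <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                   include_sire = FALSE, control = fast_ctl())
    expect_gte(full$loglik, red$loglik - 1e-4)
  }
})

test_that("average-information standard errors are finite and positive", {
  s <- small_sim(seed = 31, ngen = 6, pairs = 30)
  fit <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max)
  se <- unlist(fit$se)
  expect_true(all(is.finite(se)))
  expect_true(all(se > 0))
  expect_true(abs(fit$corr_ts) <= 1 + 1e-8)
  # reporting methods run
  expect_output(print(fit), "REML log-likelihood")
  expect_output(print(summary(fit)), "Maternal-direct")
  expect_s3_class(logLik(fit), "logLik")
  expect_length(coef(fit), fit$p)
  rf <- ranef(fit)
  expect_true(all(c("a_d", "a_s", "m", "b", "rel_d") %in% names(rf)))
  expect_equal(rf$b, 2 * rf$a_s)
  expect_lt(max(abs(fitted(fit) + residuals(fit) -
                      s$sim$litters$litter_weight_g)), 1e-10)
})

test_that("reliability reflects litter information content", {
  K <- 8
  ids <- c(paste0("d", 1:K), paste0("s", 1:K), "loner")
  ped <- pedigree(ids, rep(NA, 2 * K + 1), rep(NA, 2 * K + 1))
  lit <- data.frame(litter_id = paste0("L", 1:K),
                    dam = paste0("d", 1:K), sire = paste0("s", 1:K),
                    generation = 1, mating_age_days = 100,
                    litter_size = seq(2, 16, 2),
                    litter_weight_g = seq(2, 16, 2) * 1.8)
  G <- matrix(c(2.631, 0.596, 0.596, 0.137), 2, 2)
  bl <- mme_blup(lit, ped, G, sigma_e2 = 2.056, n_max = 22)
  dams <- bl[match(paste0("d", 1:K), bl$animal), ]
  # reliability strictly increases with litter size under the RRM
  expect_true(all(diff(dams$rel_d) > 0))
  # prediction error variance never exceeds the prior variance
  expect_true(all(bl$pev_d <= G[1, 1] + 1e-10))
  # an unphenotyped, unrelated animal carries no information
  ln <- bl[bl$animal == "loner", ]
  expect_equal(ln$rel_d, 0)
  expect_equal(ln$pev_d, G[1, 1], tolerance = 1e-10)
  expect_equal(ln$a_d, 0, tolerance = 1e-12)
  # under the average-birth-weight baseline reliability ignores litter size
  bla <- mme_blup(lit, ped, matrix(0.008), sigma_e2 = 0.03,
                  variant = "ABW", n_max = 22)
  damsa <- bla[match(paste0("d", 1:K), bla$animal), ]
  expect_lt(max(damsa$rel_d) - min(damsa$rel_d), 1e-10)
})

test_that("simulate method reproduces the fitted variance structure", {
  s <- small_sim(seed = 12, ngen = 4, pairs = 15)
  fit <- rrm_fit(s$sim$litters, s$sim$pedigree, n_max = s$cfg$n_max,
                 control = fast_ctl())
  ys <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(ys), c(fit$nlit, 3L))
  expect_true(all(is.finite(as.matrix(ys))))
})
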