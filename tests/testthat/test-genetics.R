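test_that("slope and maternal-direct parameterizations interconvert", {
  sl <- slope_from_maternal_direct(1, 1, 0)
  expect_equal(sl[c("sigma_t2", "sigma_s2", "sigma_ts")],
               list(sigma_t2 = 1.25, sigma_s2 = 0.25, sigma_ts = 0.25))
  # pure direct inheritance implies a dam-sire correlation of 1
  sl2 <- slope_from_maternal_direct(0, 4, 0)
  expect_equal(sl2$sigma_t2, 1)
  expect_equal(sl2$sigma_s2, 1)
  expect_equal(sl2$sigma_ts, 1)

  md <- maternal_direct_from_slope(1.25, 0.25, 0.25)
  expect_equal(md[c("sigma_m2", "sigma_d2", "sigma_md")],
               list(sigma_m2 = 1, sigma_d2 = 1, sigma_md = 0))

  z <- maternal_direct_from_slope(0, 0, 0)
  expect_equal(unlist(z[1:3]), c(sigma_m2 = 0, sigma_d2 = 0, sigma_md = 0))

  # published growth-line slope estimates, mapped to the maternal-direct
  # scale by the linear transformation and checked against the congruence
  md6 <- suppressWarnings(maternal_direct_from_slope(7.433, 4.976, -2.181))
  expect_equal(md6$sigma_d2, 19.904)
  expect_equal(md6$sigma_md, -14.314)
  expect_equal(md6$sigma_m2, 16.771)
  K <- matrix(c(1, 0, 0.5, 0.5), 2, 2)
  G <- matrix(c(7.433, -2.181, -2.181, 4.976), 2, 2)
  M <- solve(K) %*% G %*% t(solve(K))
  expect_equal(md6$M, M)

  # exact mutual inverses on random PSD inputs
  set.seed(1)
  for (i in 1:25) {
    L <- matrix(c(rlnorm(1), rnorm(1), 0, rlnorm(1)), 2, 2)
    M <- L %*% t(L)
    sl <- slope_from_maternal_direct(M[1, 1], M[2, 2], M[1, 2])
    back <- maternal_direct_from_slope(sl$sigma_t2, sl$sigma_s2, sl$sigma_ts)
    expect_equal(c(back$sigma_m2, back$sigma_d2, back$sigma_md),
                 c(M[1, 1], M[2, 2], M[1, 2]), tolerance = 1e-12)
  }
})

test_that("effect-level transform is an exact involution pair", {
  set.seed(2)
  a_d <- rnorm(50); a_s <- rnorm(50)
  md <- maternal_direct_effects(a_d, a_s)
  sl <- slope_effects(md$m, md$b)
  expect_equal(sl$a_d, a_d, tolerance = 1e-15)
  expect_identical(sl$a_s, a_s)
})

test_that("genetic variance scales quadratically in litter size", {
  v_max <- genetic_variance_at_ls(2.631, 0.137, 22, 22)
  expect_equal(unname(v_max), c(2.631 + 0.137, 2.631, 0.137))
  v_half <- genetic_variance_at_ls(2.631, 0.137, 11, 22)
  expect_equal(unname(v_half), unname(v_max) / 4)
  expect_error(genetic_variance_at_ls(1, 1, 0, 22), "positive")
  # covariance-inclusive variant of the total
  vc <- genetic_variance_at_ls(2.631, 0.137, 22, 22, sigma_ts = 0.596,
                               include_covariance = TRUE)
  expect_equal(unname(vc["total"]), 2.631 + 0.137 + 2 * 0.596)
})

test_that("heritability formulas behave as the theory says", {
  h0 <- heritability_at_ls(0, 0, 2, 10, 22)
  expect_equal(unname(h0), c(0, 0, 0))
  st <- 2.631; ss <- 0.137; se <- 2.056
  h <- vapply(1:22, function(n) heritability_at_ls(st, ss, se, n, 22),
              numeric(3))
  # dam + sire = total, everywhere
  expect_equal(h["h2_dam", ] + h["h2_sire", ], h["h2_tot", ])
  # strictly increasing in litter size
  expect_true(all(diff(h["h2_tot", ]) > 0))
  # at the maximum litter size the x-scaling drops out
  expect_equal(unname(h["h2_tot", 22]), (st + ss) / (st + ss + se))
})

test_that("average heritability is a weighted mean over litter sizes", {
  st <- 2.631; ss <- 0.137; se <- 2.056
  pm <- average_heritability(st, ss, se, c(`11` = 1), 22)
  expect_equal(pm, heritability_at_ls(st, ss, se, 11, 22))
  # empirical litter sizes as raw integers
  draws <- rep(c(9, 11, 13), c(2, 5, 3))
  avg <- average_heritability(st, ss, se, draws, 22)
  man <- (2 * heritability_at_ls(st, ss, se, 9, 22) +
            5 * heritability_at_ls(st, ss, se, 11, 22) +
            3 * heritability_at_ls(st, ss, se, 13, 22)) / 10
  expect_equal(avg, man)
  # discretized normal like the control line: Jensen gap is small
  set.seed(3)
  ls <- pmin(pmax(round(rnorm(5000, 11.61, 2.98)), 1), 22)
  avg2 <- average_heritability(st, ss, se, ls, 22)
  at_mean <- heritability_at_ls(st, ss, se, mean(ls), 22)
  expect_lt(abs(avg2[["h2_tot"]] - at_mean[["h2_tot"]]), 0.02)
  expect_error(average_heritability(st, ss, se, numeric(0), 22), "empty")
})

test_that("litters of different size are genetically the same trait", {
  expect_equal(litter_genetic_correlation(5, 22, 2.631, 0.137), 1)
  expect_equal(litter_genetic_correlation(7, 7, 0.3, 0.01), 1)
  set.seed(4)
  for (i in 1:20) {
    ns <- sample.int(30, 2)
    expect_equal(litter_genetic_correlation(ns[1], ns[2], rlnorm(1),
                                            rlnorm(1)), 1)
  }
  expect_true(is.na(litter_genetic_correlation(5, 9, 0, 0)))
})

test_that("standard errors rescale linearly or quadratically in x", {
  expect_equal(scale_se_to_ls(0.05, 22, 22), 0.05)
  expect_equal(scale_se_to_ls(0.05, 11, 22), 0.025)
  expect_equal(scale_se_to_ls(0.05, 11, 22, mode = "x_squared"), 0.0125)
})

test_that("heritability trajectories come out of fits and components", {
  hc <- heritability(sigma_t2 = 2.631, sigma_s2 = 0.137, sigma_e2 = 2.056,
                     n_max = 22)
  expect_s3_class(hc, "rrm_h2_curve")
  expect_equal(nrow(hc), 22)
  expect_equal(hc$h2_tot[22], (2.631 + 0.137) / (2.631 + 0.137 + 2.056))
})
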