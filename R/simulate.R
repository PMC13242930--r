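# Synthetic pedigree and litter-weight data with the statistical structure
# the random regression model assumes: discrete non-overlapping generations,
# one litter per breeding pair, pedigree-correlated parental slope effects,
# and litter weight y = fixed + x (a_d + a_s) + e with x = n / n_max.

#' Simulation configuration
#'
#' Bundles and validates all simulator settings. Defaults emulate an
#' unselected control mouse line: 40+ generations of 125 breeding pairs
#' with a 1:1 mating ratio, litter sizes around 11 with a maximum of 22,
#' and slope (co)variances of a few g^2 at x = 1.
#'
#' @param n_generations number of litter cohorts.
#' @param pairs_per_generation breeding pairs per cohort.
#' @param truth list of variance components at x = 1: either
#'   `sigma_t2`, `sigma_s2`, `sigma_ts`, `sigma_e2`, or maternal-direct
#'   `sigma_m2`, `sigma_d2`, `sigma_md` plus `sigma_e2` (converted through
#'   the slope transformation).
#' @param n_max maximum litter size (scaling constant).
#' @param ls_mean,ls_sd moments of the discretized normal litter-size
#'   distribution, truncated to `[1, n_max]`.
#' @param ls_table optional named probability table over litter sizes,
#'   overriding the discretized normal.
#' @param age_mean,age_sd dam mating age distribution (days).
#' @param generation_effect_sd SD of the fixed generation effects.
#' @param beta_age coefficients of the linear and quadratic Legendre age
#'   terms in the simulated mean.
#' @param beta0 fixed regression of litter weight on x = n/n_max (g at
#'   x = 1); roughly average birth weight times n_max.
#' @param intercept overall mean offset (g).
#' @param sire_double_fraction fraction of sires mated to two dams.
#' @param avoid_full_sibs forbid matings that share a parent?
#' @param mode `"rrm_exact"` (litter residual independent of litter size),
#'   `"pup_level"` (per-pup direct Mendelian deviations and measurement
#'   noise summed, so the residual variance grows with litter size), or
#'   `"bivariate"` (joint litter weight / litter size simulation; requires
#'   `truth_biv`).
#' @param truth_biv for `mode = "bivariate"`: list with `G3` (3x3 genetic
#'   covariance of dam slope, sire slope and dam litter-size effect) and
#'   `R2` (2x2 residual covariance of the two traits of one litter).
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_generations = 40, pairs_per_generation = 125,
                       truth = list(sigma_t2 = 2.6, sigma_s2 = 0.14,
                                    sigma_ts = 0.6, sigma_e2 = 2.1),
                       n_max = 22, ls_mean = 11.61, ls_sd = 2.98,
                       ls_table = NULL,
                       age_mean = 90, age_sd = 25,
                       generation_effect_sd = 1,
                       beta_age = c(0.5, -0.3), beta0 = 39, intercept = 0,
                       sire_double_fraction = 0, avoid_full_sibs = TRUE,
                       mode = c("rrm_exact", "pup_level", "bivariate"),
                       truth_biv = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (!is.null(truth$sigma_m2)) {
    sl <- slope_from_maternal_direct(truth$sigma_m2, truth$sigma_d2,
                                     truth$sigma_md)
    truth <- list(sigma_t2 = sl$sigma_t2, sigma_s2 = sl$sigma_s2,
                  sigma_ts = sl$sigma_ts, sigma_e2 = truth$sigma_e2)
  }
  G <- matrix(c(truth$sigma_t2, truth$sigma_ts, truth$sigma_ts,
                truth$sigma_s2), 2, 2,
              dimnames = list(c("dam", "sire"), c("dam", "sire")))
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("truth G must be positive semidefinite")
  stopifnot(truth$sigma_e2 > 0, n_generations >= 1,
            pairs_per_generation >= 2, n_max >= 1,
            sire_double_fraction >= 0, sire_double_fraction <= 0.5)
  if (!is.null(ls_table)) {
    ns <- as.numeric(names(ls_table))
    if (any(ns < 1 | ns > n_max)) stop("ls_table support outside [1, n_max]")
    if (abs(sum(ls_table) - 1) > 1e-8) stop("ls_table must sum to 1")
  }
  if (mode == "bivariate") {
    if (is.null(truth_biv)) stop("mode 'bivariate' requires truth_biv")
    stopifnot(all(dim(as.matrix(truth_biv$G3)) == c(3, 3)),
              all(dim(as.matrix(truth_biv$R2)) == c(2, 2)))
  }
  structure(list(n_generations = n_generations,
                 pairs_per_generation = pairs_per_generation,
                 truth = truth, G = G, n_max = n_max,
                 ls_mean = ls_mean, ls_sd = ls_sd, ls_table = ls_table,
                 age_mean = age_mean, age_sd = age_sd,
                 generation_effect_sd = generation_effect_sd,
                 beta_age = beta_age, beta0 = beta0, intercept = intercept,
                 sire_double_fraction = sire_double_fraction,
                 avoid_full_sibs = avoid_full_sibs, mode = mode,
                 truth_biv = truth_biv, seed = as.integer(seed)),
            class = "sim_config")
}

#' Load a named scenario preset
#'
#' Reads one of the YAML presets shipped with the package
#' (`fztdu_like`, `du6_like`, `high_fecundity_like`) and turns it into a
#' [sim_config()].
#'
#' @param name preset name.
#' @param ... overrides passed on to [sim_config()].
#' @export
sim_preset <- function(name = c("fztdu_like", "du6_like",
                                "high_fecundity_like"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "rrmlw")
  if (path == "") stop("preset file not found")
  args <- yaml::read_yaml(path)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Pair males and females avoiding shared parents; returns permutation of
# the female vector, or NULL when no valid pairing was found.
.pair_avoiding_sibs <- function(msire, mdam, fsire, fdam, tries = 200) {
  P <- length(fsire)
  for (t in seq_len(tries)) {
    perm <- sample.int(P)
    bad <- which(msire == fsire[perm] | mdam == fdam[perm] |
                   msire == fdam[perm] | mdam == fsire[perm])
    if (!length(bad)) return(perm)
    # local repair: reshuffle the conflicted positions
    for (r in seq_len(20)) {
      if (length(bad) < 2L) break
      perm[bad] <- perm[sample(bad)]
      bad <- which(msire == fsire[perm] | mdam == fdam[perm] |
                     msire == fdam[perm] | mdam == fsire[perm])
      if (!length(bad)) return(perm)
    }
  }
  NULL
}

#' Simulate a discrete-generation pedigree with one litter per pair
#'
#' Generation 0 consists of unrelated founders; every later cohort's
#' breeders are sampled from the previous cohort's litters (uniformly over
#' litters) and paired at random, optionally avoiding matings that share a
#' parent and optionally letting a fraction of sires mate twice.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped` (an [pedigree()]) and `skeleton`, a data.frame
#'   of prospective litters (`litter_id`, `dam`, `sire`, `generation`).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  P <- cfg$pairs_per_generation
  ngen <- cfg$n_generations
  fmt <- function(k) sprintf("A%06d", k)

  n_sires0 <- max(1L, P - round(cfg$sire_double_fraction * P))
  # animal bookkeeping
  id <- character(0); sire <- character(0); dam <- character(0)
  gen <- integer(0)
  counter <- 0L
  new_animals <- function(k, s, d, g) {
    ids <- fmt(counter + seq_len(k))
    counter <<- counter + k
    id <<- c(id, ids); sire <<- c(sire, s); dam <<- c(dam, d)
    gen <<- c(gen, rep(g, k))
    ids
  }
  males <- new_animals(n_sires0, rep(NA_character_, n_sires0),
                       rep(NA_character_, n_sires0), 0L)
  females <- new_animals(P, rep(NA_character_, P), rep(NA_character_, P), 0L)

  lit_dam <- character(0); lit_sire <- character(0); lit_gen <- integer(0)
  for (g in seq_len(ngen)) {
    # mate: expand sires so that each pair has one sire, some sires twice
    sire_for_pair <- if (length(males) < P) {
      c(males, sample(males, P - length(males)))
    } else males[seq_len(P)]
    if (cfg$avoid_full_sibs && g > 1L) {
      midx <- match(sire_for_pair, id)
      fidx <- match(females, id)
      perm <- .pair_avoiding_sibs(sire[midx], dam[midx],
                                  sire[fidx], dam[fidx])
      if (is.null(perm))
        stop("population collapse: no sib-avoiding pairing found in ",
             "generation ", g)
      females <- females[perm]
    }
    lit_dam <- c(lit_dam, females)
    lit_sire <- c(lit_sire, sire_for_pair)
    lit_gen <- c(lit_gen, rep(g, P))
    if (g < ngen) {
      # next cohort's breeders: uniform over this cohort's litters
      n_sires <- max(1L, P - round(cfg$sire_double_fraction * P))
      pick <- function(k) {
        j <- sample.int(P, k, replace = TRUE)
        new_animals(k, sire_for_pair[j], females[j], g)
      }
      males <- pick(n_sires)
      females <- pick(P)
    }
  }
  ped <- pedigree(id, sire, dam, generation = gen)
  skeleton <- data.frame(
    litter_id = sprintf("L%06d", seq_along(lit_dam)),
    dam = lit_dam, sire = lit_sire, generation = lit_gen,
    stringsAsFactors = FALSE)
  list(ped = ped, skeleton = skeleton)
}

#' Simulate breeding values down a pedigree
#'
#' Draws multivariate animal effects with covariance `G` (x) `A`: founders
#' from N(0, G), descendants as the parent average plus a Mendelian
#' sampling deviation with covariance d_i G, d_i = 0.5 - 0.25 (F_s + F_d)
#' (F = -1 for an unknown parent), so inbreeding shrinks the within-family
#' variance.
#'
#' @param ped an [pedigree()].
#' @param G k x k positive semidefinite genetic covariance matrix; for the
#'   litter-weight model, 2 x 2 over the dam and sire slope effects.
#' @param seed optional seed.
#' @return numeric matrix (animals x k), column names from `G`.
#' @export
simulate_breeding_values <- function(ped, G, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ped, "rrm_pedigree"))
  G <- as.matrix(G)
  k <- nrow(G)
  n <- ped$n
  ev <- eigen(G, symmetric = TRUE)
  Lg <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  Fv <- inbreeding(ped)
  fs <- ifelse(ped$sire > 0L, Fv[pmax(ped$sire, 1L)], -1)
  fd <- ifelse(ped$dam > 0L, Fv[pmax(ped$dam, 1L)], -1)
  dms <- 0.5 - 0.25 * (fs + fd)
  u <- matrix(0, n, k)
  for (lv in sort(unique(ped$depth))) {
    idx <- which(ped$depth == lv)
    ms <- matrix(stats::rnorm(length(idx) * k), length(idx), k) %*% t(Lg) *
      sqrt(dms[idx])
    pa <- matrix(0, length(idx), k)
    hs <- ped$sire[idx] > 0L
    hd <- ped$dam[idx] > 0L
    if (any(hs)) pa[hs, ] <- pa[hs, , drop = FALSE] +
        0.5 * u[ped$sire[idx][hs], , drop = FALSE]
    if (any(hd)) pa[hd, ] <- pa[hd, , drop = FALSE] +
        0.5 * u[ped$dam[idx][hd], , drop = FALSE]
    u[idx, ] <- pa + ms
  }
  colnames(u) <- colnames(G)
  rownames(u) <- ped$id
  u
}

#' Simulate litter records
#'
#' Fills a litter skeleton with mating ages, litter sizes and litter
#' weights under the configured truth. In `rrm_exact` mode the residual is
#' a single N(0, sigma_e2) draw per litter; in `pup_level` mode each pup
#' contributes its own direct Mendelian deviation and measurement noise, so
#' the litter residual variance increases with litter size; in `bivariate`
#' mode litter size itself carries a genetic dam effect and a residual
#' correlated with the weight residual.
#'
#' @param ped an [pedigree()].
#' @param skeleton litter skeleton from [simulate_pedigree()].
#' @param effects matrix of animal effects from
#'   [simulate_breeding_values()] (2 columns, or 3 in bivariate mode).
#' @param cfg the [sim_config()].
#' @return data.frame of litter records in the canonical schema.
#' @export
simulate_litters <- function(ped, skeleton, effects, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nl <- nrow(skeleton)
  dam_i <- match(skeleton$dam, ped$id)
  sire_i <- match(skeleton$sire, ped$id)
  age <- pmax(round(stats::rnorm(nl, cfg$age_mean, cfg$age_sd)), 42)
  gens <- sort(unique(skeleton$generation))
  alpha <- stats::rnorm(length(gens), 0, cfg$generation_effect_sd)
  names(alpha) <- as.character(gens)
  agerange <- cfg$age_mean + c(-4, 4) * cfg$age_sd
  P <- legendre_age_covariates(pmin(pmax(age, agerange[1]), agerange[2]),
                               agerange, order = 2)

  if (cfg$mode == "bivariate") {
    R2 <- as.matrix(cfg$truth_biv$R2)
    ee <- matrix(stats::rnorm(2 * nl), nl, 2) %*% chol(R2)
    c_dam <- effects[dam_i, 3]
    n <- pmin(pmax(round(cfg$ls_mean + c_dam + ee[, 2]), 1), cfg$n_max)
    e1 <- ee[, 1]
  } else {
    n <- if (!is.null(cfg$ls_table)) {
      as.integer(sample(names(cfg$ls_table), nl, replace = TRUE,
                        prob = cfg$ls_table))
    } else {
      pmin(pmax(round(stats::rnorm(nl, cfg$ls_mean, cfg$ls_sd)), 1),
           cfg$n_max)
    }
    e1 <- if (cfg$mode == "pup_level") {
      sigma_pup2 <- cfg$truth$sigma_e2 / cfg$ls_mean +
        0.5 * (4 * cfg$truth$sigma_s2) / cfg$n_max^2
      stats::rnorm(nl, 0, sqrt(n * sigma_pup2))
    } else {
      stats::rnorm(nl, 0, sqrt(cfg$truth$sigma_e2))
    }
  }
  x <- n / cfg$n_max
  y <- cfg$intercept + alpha[as.character(skeleton$generation)] +
    drop(P %*% cfg$beta_age) + cfg$beta0 * x +
    x * (effects[dam_i, 1] + effects[sire_i, 2]) + e1
  # weights are positive by definition; the floor only ever binds for
  # single-pup litters in the far tail
  y <- pmax(y, 0.1)
  data.frame(litter_id = skeleton$litter_id, dam = skeleton$dam,
             sire = skeleton$sire, generation = skeleton$generation,
             mating_age_days = age, litter_size = as.integer(n),
             litter_weight_g = as.numeric(y), stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: pedigree, breeding values and litter records in one
#' call, all driven by `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree`, `litters`, `effects` (data.frame with
#'   slope effects and the recovered maternal/direct breeding values),
#'   `truth` and `config`.
#' @export
simulate_dataset <- function(cfg) {
  sk <- simulate_pedigree(cfg)  # also sets the seed
  Gsim <- if (cfg$mode == "bivariate") as.matrix(cfg$truth_biv$G3) else cfg$G
  eff <- simulate_breeding_values(sk$ped, Gsim)
  litters <- simulate_litters(sk$ped, sk$skeleton, eff, cfg)
  md <- maternal_direct_effects(eff[, 1], eff[, 2])
  effects <- data.frame(animal = sk$ped$id, a_d = eff[, 1], a_s = eff[, 2],
                        m = md$m, b = md$b, stringsAsFactors = FALSE)
  if (cfg$mode == "bivariate") effects$c_ls <- eff[, 3]
  list(pedigree = sk$ped, litters = litters, effects = effects,
       truth = cfg$truth, config = cfg)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` datasets under `cfg`, refits the random
#' regression model on each, and summarizes bias, empirical and reported
#' standard errors, and 2-SE coverage per variance component. Optionally
#' also runs the sire likelihood-ratio test per replicate.
#'
#' @param cfg a [sim_config()].
#' @param n_replicates number of simulation replicates.
#' @param include_rlrt also fit the dam-only model and run [rlrt_sire()]?
#' @param alpha significance level for the RLRT rejection count.
#' @param control a [rrm_control()] for the fits.
#' @return object of class `rrm_recovery`: list with `summary` (per
#'   component), `estimates` (per replicate), and optionally `rlrt`.
#' @export
recovery_experiment <- function(cfg, n_replicates = 20, include_rlrt = FALSE,
                                alpha = 0.05,
                                control = rrm_control(pev = FALSE)) {
  stopifnot(inherits(cfg, "sim_config"))
  comp <- c("sigma_t2", "sigma_s2", "sigma_ts", "sigma_e2")
  truth <- unlist(cfg$truth)[comp]
  est <- matrix(NA_real_, n_replicates, 4, dimnames = list(NULL, comp))
  ses <- est
  rl <- data.frame(statistic = rep(NA_real_, n_replicates),
                   p_value = NA_real_, significant = NA)
  failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    sim <- simulate_dataset(cfg_r)
    fit <- tryCatch(
      rrm_fit(sim$litters, sim$pedigree, variant = "RRM",
              n_max = cfg$n_max, control = control),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    est[r, ] <- unlist(fit$varcomp)[comp]
    ses[r, ] <- unlist(fit$se)[comp]
    if (include_rlrt) {
      red <- tryCatch(
        rrm_fit(sim$litters, sim$pedigree, variant = "RRM",
                include_sire = FALSE, n_max = cfg$n_max, control = control),
        error = function(e) NULL)
      if (!is.null(red)) {
        tst <- rlrt_sire(fit, red, alpha = alpha)
        rl$statistic[r] <- tst$statistic
        rl$p_value[r] <- tst$p_value
        rl$significant[r] <- tst$significant
      }
    }
  }
  ok <- stats::complete.cases(est)
  summ <- data.frame(
    component = comp, truth = truth,
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth,
    empirical_se = apply(est[ok, , drop = FALSE], 2, stats::sd),
    mean_reported_se = colMeans(ses[ok, , drop = FALSE], na.rm = TRUE),
    coverage_2se = colMeans(abs(est[ok, , drop = FALSE] -
                                  matrix(truth, sum(ok), 4, byrow = TRUE)) <=
                              2 * ses[ok, , drop = FALSE], na.rm = TRUE),
    row.names = NULL)
  structure(list(summary = summ, estimates = as.data.frame(est),
                 reported_se = as.data.frame(ses),
                 rlrt = if (include_rlrt) rl else NULL,
                 n_replicates = n_replicates, failed = failed,
                 config = cfg),
            class = "rrm_recovery")
}

#' @export
print.rrm_recovery <- function(x, ...) {
  cat("Parameter recovery over", x$n_replicates, "replicates (",
      x$failed, "failed )\n")
  print(x$summary, digits = 4)
  if (!is.null(x$rlrt)) {
    cat(sprintf("RLRT rejection rate at alpha: %.3f\n",
                mean(x$rlrt$significant, na.rm = TRUE)))
  }
  invisible(x)
}
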