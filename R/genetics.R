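# Closed-form genetic algebra of the litter-weight random regression model.
#
# A parent's dam effect on litter weight is a_d = m + b/2 and its sire
# effect a_s = b/2, where m and b are the maternal and direct breeding
# values for individual birth weight. In matrix form (a_d, a_s)' =
# K' (m, b)' with K' = [[1, 1/2], [0, 1/2]], which is invertible, so the
# slope and maternal-direct parameterizations carry the same information.

.KPRIME <- matrix(c(1, 0, 0.5, 0.5), 2, 2)

#' Slope (co)variances from maternal-direct components
#'
#' Applies the congruence G = K' M K with M = [[sigma_m2, sigma_md],
#' [sigma_md, sigma_d2]], giving
#' sigma_t2 = sigma_m2 + sigma_d2/4 + sigma_md,
#' sigma_ts = sigma_md/2 + sigma_d2/4, sigma_s2 = sigma_d2/4.
#'
#' @param sigma_m2 maternal genetic variance.
#' @param sigma_d2 direct genetic variance.
#' @param sigma_md maternal-direct genetic covariance.
#' @return list with `sigma_t2`, `sigma_s2`, `sigma_ts` and the 2x2 matrix
#'   `G`.
#' @export
slope_from_maternal_direct <- function(sigma_m2, sigma_d2, sigma_md) {
  M <- matrix(c(sigma_m2, sigma_md, sigma_md, sigma_d2), 2, 2)
  G <- .KPRIME %*% M %*% t(.KPRIME)
  list(sigma_t2 = G[1, 1], sigma_s2 = G[2, 2], sigma_ts = G[1, 2], G = G)
}

#' Maternal-direct components from slope (co)variances
#'
#' Inverse of [slope_from_maternal_direct()]:
#' sigma_d2 = 4 sigma_s2, sigma_md = 2 (sigma_ts - sigma_s2),
#' sigma_m2 = sigma_t2 - 2 sigma_ts + sigma_s2.
#'
#' @param sigma_t2 dam-slope genetic variance (at x = 1).
#' @param sigma_s2 sire-slope genetic variance.
#' @param sigma_ts dam-sire genetic covariance.
#' @return list with `sigma_m2`, `sigma_d2`, `sigma_md` and the implied 2x2
#'   matrix `M`; warns when `M` is indefinite (estimation noise).
#' @export
maternal_direct_from_slope <- function(sigma_t2, sigma_s2, sigma_ts) {
  G <- matrix(c(sigma_t2, sigma_ts, sigma_ts, sigma_s2), 2, 2)
  Kinv <- solve(.KPRIME)
  M <- Kinv %*% G %*% t(Kinv)
  out <- list(sigma_m2 = M[1, 1], sigma_d2 = M[2, 2], sigma_md = M[1, 2],
              M = M)
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    warning("implied maternal-direct matrix is indefinite")
  out
}

#' Convert parental slope effects to maternal/direct breeding values
#'
#' Applies the inverse transformation (m, b)' = K'^-1 (a_d, a_s)', i.e.
#' m = a_d - a_s and b = 2 a_s, elementwise over animals.
#'
#' @param a_d,a_s dam and sire slope effects (same length).
#' @return list with vectors `m` and `b`.
#' @export
maternal_direct_effects <- function(a_d, a_s) {
  list(m = a_d - a_s, b = 2 * a_s)
}

#' Convert maternal/direct breeding values to parental slope effects
#'
#' @param m,b maternal and direct breeding values.
#' @return list with vectors `a_d = m + b/2` and `a_s = b/2`.
#' @export
slope_effects <- function(m, b) {
  list(a_d = m + b / 2, a_s = b / 2)
}

#' Genetic variance of litter weight at a given litter size
#'
#' At litter size n (x = n/n_max) the genetic variance of a litter is
#' x^2 (sigma_t2 + sigma_s2), the dam part x^2 sigma_t2 and the sire part
#' x^2 sigma_s2. The default total deliberately omits the dam-sire
#' covariance, matching the definition used for the heritability
#' trajectories; `include_covariance = TRUE` adds 2 x^2 sigma_ts, the
#' variance of the sum of the two parental contributions of one mating.
#'
#' @param sigma_t2,sigma_s2 slope genetic variances at x = 1.
#' @param n litter size (positive, may be fractional for evaluation at a
#'   mean litter size); must not exceed `n_max`.
#' @param n_max maximum litter size of the scaling.
#' @param sigma_ts dam-sire covariance, used only when
#'   `include_covariance = TRUE`.
#' @param include_covariance include 2 x^2 sigma_ts in the total?
#' @return named vector `c(total, dam, sire)`.
#' @export
genetic_variance_at_ls <- function(sigma_t2, sigma_s2, n, n_max,
                                   sigma_ts = 0, include_covariance = FALSE) {
  if (any(n <= 0)) stop("litter size must be positive")
  if (any(n > n_max)) stop("litter size exceeds n_max")
  x <- n / n_max
  tot <- x^2 * (sigma_t2 + sigma_s2)
  if (include_covariance) tot <- tot + 2 * x^2 * sigma_ts
  c(total = tot, dam = x^2 * sigma_t2, sire = x^2 * sigma_s2)
}

#' Litter-size-dependent heritability
#'
#' With x = n/n_max, the dam heritability is
#' x^2 sigma_t2 / (x^2 (sigma_t2 + sigma_s2) + sigma_e2), the sire
#' heritability is the analogue with sigma_s2 in the numerator, and the
#' total heritability is their sum. Heritability grows with litter size
#' because a larger litter carries more information about the parents'
#' genetic effects.
#'
#' @param sigma_t2,sigma_s2 slope genetic variances at x = 1.
#' @param sigma_e2 residual variance (> 0).
#' @param n litter size (positive real, <= n_max).
#' @param n_max maximum litter size of the scaling.
#' @return named vector `c(h2_dam, h2_sire, h2_tot)`.
#' @export
heritability_at_ls <- function(sigma_t2, sigma_s2, sigma_e2, n, n_max) {
  stopifnot(sigma_e2 > 0)
  if (any(n <= 0) || any(n > n_max)) stop("n must be in (0, n_max]")
  x <- n / n_max
  den <- x^2 * (sigma_t2 + sigma_s2) + sigma_e2
  c(h2_dam = x^2 * sigma_t2 / den,
    h2_sire = x^2 * sigma_s2 / den,
    h2_tot = x^2 * (sigma_t2 + sigma_s2) / den)
}

#' Average heritability over a litter-size distribution
#'
#' Weighted mean of [heritability_at_ls()] over litter sizes, e.g. over the
#' empirical litter-size frequencies of the fitted dataset.
#'
#' @param sigma_t2,sigma_s2,sigma_e2 variance components.
#' @param weights named numeric vector: names are litter sizes, values are
#'   probabilities (must sum to 1 within tolerance) -- or an integer vector
#'   of observed litter sizes, in which case empirical frequencies are used.
#' @param n_max maximum litter size of the scaling.
#' @return named vector `c(h2_dam, h2_sire, h2_tot)`.
#' @export
average_heritability <- function(sigma_t2, sigma_s2, sigma_e2, weights,
                                 n_max) {
  if (is.null(names(weights))) {
    tb <- table(weights)
    w <- as.numeric(tb) / sum(tb)
    ns <- as.numeric(names(tb))
  } else {
    w <- as.numeric(weights)
    ns <- as.numeric(names(weights))
    if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  }
  if (!length(ns)) stop("empty litter-size distribution")
  H <- vapply(ns, function(n)
    heritability_at_ls(sigma_t2, sigma_s2, sigma_e2, n, n_max), numeric(3))
  drop(H %*% w)
}

#' Genetic correlation between litters of different size
#'
#' The genetic covariance of two litters of sizes n_i and n_j from base
#' parents is n_i n_j (sigma_t2 + sigma_s2) while their variances are
#' n_i^2 and n_j^2 times the same sum, so the correlation is identically 1:
#' litter weight at different litter sizes is genetically the same trait,
#' unlike in random regression models over age or lactation trajectories.
#' Implemented as the covariance/variance ratio so the cancellation is
#' computed, not asserted.
#'
#' @param n_i,n_j litter sizes (>= 1).
#' @param sigma_t2,sigma_s2 slope genetic variances.
#' @return 1, or `NA` when the genetic variance is zero.
#' @export
litter_genetic_correlation <- function(n_i, n_j, sigma_t2, sigma_s2) {
  stopifnot(n_i >= 1, n_j >= 1)
  sa <- sigma_t2 + sigma_s2
  if (sa <= 0) return(NA_real_)
  (n_i * n_j * sa) / sqrt((n_i^2 * sa) * (n_j^2 * sa))
}

#' Rescale a standard error from x = 1 to another litter size
#'
#' Reported standard errors of the genetic (co)variances apply at the
#' maximum litter size (x = 1). The default mode multiplies by x = n/n_max;
#' an `x_squared` mode is provided as well, matching the quadratic scaling
#' of the variances themselves (see the methods vignette for the
#' distinction).
#'
#' @param se standard error at x = 1 (>= 0).
#' @param n litter size.
#' @param n_max maximum litter size.
#' @param mode `"linear_x"` (default) or `"x_squared"`.
#' @return rescaled standard error.
#' @export
scale_se_to_ls <- function(se, n, n_max, mode = c("linear_x", "x_squared")) {
  mode <- match.arg(mode)
  stopifnot(se >= 0)
  x <- standardize_litter_size(n, n_max)
  if (mode == "linear_x") se * x else se * x^2
}

#' Heritability trajectory over litter size
#'
#' Evaluates dam, sire and total heritability on the grid 1..n_max, either
#' from a fitted model or from explicit components.
#'
#' @param object an `rrm_fit` (RRM with sire effect), or missing when
#'   components are given explicitly.
#' @param sigma_t2,sigma_s2,sigma_e2 explicit components (used when
#'   `object` is missing).
#' @param n_max maximum litter size (taken from the fit when available).
#' @return data.frame of class `rrm_h2_curve` with columns `n`, `h2_dam`,
#'   `h2_sire`, `h2_tot`.
#' @export
heritability <- function(object = NULL, sigma_t2 = NULL, sigma_s2 = NULL,
                         sigma_e2 = NULL, n_max = NULL) {
  if (!is.null(object)) {
    stopifnot(inherits(object, "rrm_fit"))
    sigma_t2 <- object$varcomp$sigma_t2
    sigma_s2 <- object$varcomp$sigma_s2 %||% 0
    sigma_e2 <- object$varcomp$sigma_e2
    if (is.null(n_max)) n_max <- object$n_max
  }
  stopifnot(!is.null(sigma_t2), !is.null(sigma_e2), !is.null(n_max))
  if (is.null(sigma_s2)) sigma_s2 <- 0
  grid <- seq_len(n_max)
  H <- t(vapply(grid, function(n)
    heritability_at_ls(sigma_t2, sigma_s2, sigma_e2, n, n_max), numeric(3)))
  out <- data.frame(n = grid, H)
  class(out) <- c("rrm_h2_curve", "data.frame")
  out
}

#' @export
plot.rrm_h2_curve <- function(x, ...) {
  graphics::matplot(x$n, cbind(x$h2_tot, x$h2_dam, x$h2_sire), type = "l",
                    lty = 1:3, col = 1, xlab = "litter size",
                    ylab = "heritability", ylim = c(0, 1), ...)
  graphics::legend("topleft", c("total", "dam", "sire"), lty = 1:3, bty = "n")
  invisible(x)
}
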