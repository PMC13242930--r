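# Model battery: restricted likelihood ratio test for the sire component
# and the bivariate litter weight / litter size model.

#' RLRT from two restricted log-likelihoods
#'
#' The test statistic is 2 (RL_full - RL_reduced), referred to a chi-square
#' distribution with `df` degrees of freedom (2 for the joint removal of
#' the sire variance and the dam-sire covariance). Small negative
#' statistics (within `tol`) are clamped to zero with a warning; larger
#' negatives raise an error because they indicate a non-converged full fit.
#'
#' @param rl_full,rl_reduced restricted log-likelihoods.
#' @param df degrees of freedom (default 2).
#' @param alpha significance level.
#' @param tol clamping tolerance for negative statistics; the default
#'   matches twice the optimizer's relative function tolerance at typical
#'   restricted-likelihood magnitudes and is far below any chi-square
#'   critical value.
#' @return list of class `rrm_rlrt` with `rl_full`, `rl_reduced`,
#'   `statistic`, `df`, `p_value`, `significant`.
#' @export
rlrt_from_loglik <- function(rl_full, rl_reduced, df = 2, alpha = 0.05,
                             tol = max(1e-4, 2e-7 * abs(rl_full))) {
  stat <- 2 * (rl_full - rl_reduced)
  if (stat < 0) {
    if (stat < -tol)
      stop("full-model likelihood below reduced-model likelihood (",
           format(stat), "); refit the full model from the reduced solution")
    warning("negative RLRT statistic within tolerance clamped to 0")
    stat <- 0
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(rl_full = rl_full, rl_reduced = rl_reduced,
                 statistic = stat, df = df, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "rrm_rlrt")
}

#' Likelihood-ratio test for the sire genetic variance
#'
#' Tests the null hypothesis of no sire genetic component (trait fully
#' under maternal control) by comparing a full fit (dam + sire random
#' effects) against the reduced dam-only fit on identical data, with a
#' 2-df chi-square reference for the joint removal of sigma_s2 and
#' sigma_ts. Note the null lies on the boundary of the parameter space, so
#' the 2-df reference is conservative; [rlrt_from_loglik()] with a custom
#' `df` supports mixture-style references.
#'
#' @param fit_full `rrm_fit` with the sire block.
#' @param fit_reduced `rrm_fit` with `include_sire = FALSE`.
#' @param alpha significance level.
#' @param boundary_mixture use the 0.5 chi2(1) + 0.5 chi2(2) boundary
#'   mixture instead of the plain 2-df reference?
#' @return an `rrm_rlrt` object.
#' @export
rlrt_sire <- function(fit_full, fit_reduced, alpha = 0.05,
                      boundary_mixture = FALSE) {
  stopifnot(inherits(fit_full, "rrm_fit"), inherits(fit_reduced, "rrm_fit"))
  if (!fit_full$include_sire || fit_reduced$include_sire)
    stop("fit_full must include the sire block and fit_reduced must not")
  if (any(abs(fit_full$fingerprint - fit_reduced$fingerprint) >
          1e-8 * (abs(fit_full$fingerprint) + 1)))
    stop("fits were not computed on identical data")
  out <- rlrt_from_loglik(fit_full$loglik, fit_reduced$loglik, df = 2,
                          alpha = alpha)
  if (boundary_mixture) {
    out$p_value <- 0.5 * stats::pchisq(out$statistic, 1, lower.tail = FALSE) +
      0.5 * stats::pchisq(out$statistic, 2, lower.tail = FALSE)
    out$significant <- out$p_value < alpha
    out$df <- NA_real_
  }
  out
}

#' @export
print.rrm_rlrt <- function(x, ...) {
  cat("Restricted likelihood ratio test for the sire genetic component\n")
  cat(sprintf("  RL_red = %.2f   RL_full = %.2f\n", x$rl_reduced, x$rl_full))
  cat(sprintf("  RLRT = %.4g on %s df,  P = %.3g  (%s at alpha = %g)\n",
              x$statistic,
              if (is.na(x$df)) "mixture" else format(x$df),
              x$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

# ---- bivariate litter weight / litter size model ---------------------------

# Observation order is trait-major (all LW rows, then all LS rows); the two
# records of one litter share a 2x2 residual covariance R2. The random
# structure is G3 (x) A over the blocks (dam slope LW, sire slope LW, dam
# intercept LS) for the RRM variant, or (dam effect trait1, dam effect LS)
# for the traditional variants.

.biv_prep <- function(litters, ped, variant, n_max, age_poly_order,
                      ls_fixed_age) {
  dm1 <- build_design(litters, ped, variant = variant, n_max = n_max,
                      age_poly_order = age_poly_order,
                      include_sire = (variant == "RRM"))
  lit2 <- litters
  lit2$litter_weight_g <- as.numeric(litters$litter_size)
  dm2 <- build_design(lit2, ped, variant = "TLW", n_max = n_max,
                      age_poly_order = if (ls_fixed_age) age_poly_order else 0,
                      include_sire = FALSE)
  nlit <- dm1$nlit
  m <- dm1$m
  c1 <- ncol(dm1$X); c2 <- ncol(dm2$X)
  nb <- length(dm1$Zlist) + 1L
  # litter-indexed design rows, embedded in the common column space
  ncol_tot <- c1 + c2 + nb * m
  D1 <- cbind(dm1$X, Matrix::Matrix(0, nlit, c2, sparse = TRUE),
              do.call(cbind, unname(dm1$Zlist)),
              Matrix::Matrix(0, nlit, m, sparse = TRUE))
  D2 <- cbind(Matrix::Matrix(0, nlit, c1, sparse = TRUE), dm2$X,
              Matrix::Matrix(0, nlit, (nb - 1L) * m, sparse = TRUE),
              dm2$Zlist$dam)
  y1 <- dm1$y
  y2 <- dm2$y
  p <- c1 + c2

  M11 <- Matrix::forceSymmetric(Matrix::crossprod(D1))
  M22 <- Matrix::forceSymmetric(Matrix::crossprod(D2))
  M12 <- Matrix::crossprod(D1, D2)
  M12s <- Matrix::forceSymmetric(M12 + Matrix::t(M12))

  tri <- function(M) {
    tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
    keep <- tm@i <= tm@j
    list(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, x = tm@x[keep])
  }
  t11 <- tri(M11); t22 <- tri(M22); t12 <- tri(M12s)

  ainv <- a_inverse(ped)
  at <- as(as(ainv, "generalMatrix"), "TsparseMatrix")
  ldA <- attr(ainv, "logdet")
  ai <- at@i + 1L; aj <- at@j + 1L; ax <- at@x
  upper <- ai <= aj
  bi <- list(); bj <- list(); bx <- list(); blk <- list()
  for (k in seq_len(nb)) for (l in k:nb) {
    if (k == l) {
      ii <- p + (k - 1L) * m + ai[upper]; jj <- p + (l - 1L) * m + aj[upper]
      xx <- ax[upper]
    } else {
      ii <- p + (k - 1L) * m + ai; jj <- p + (l - 1L) * m + aj; xx <- ax
    }
    bi <- c(bi, list(ii)); bj <- c(bj, list(jj)); bx <- c(bx, list(xx))
    blk <- c(blk, list(c(k, l)))
  }
  neq <- ncol_tot
  Tm <- Matrix::sparseMatrix(
    i = c(t11$i, t22$i, t12$i, unlist(bi)),
    j = c(t11$j, t22$j, t12$j, unlist(bj)),
    x = c(t11$x, t22$x, t12$x, unlist(bx)),
    dims = c(neq, neq), symmetric = TRUE)
  tkey <- (rep(seq_len(neq), diff(Tm@p)) - 1) * neq + Tm@i + 1
  pos <- function(t) match((t$j - 1) * neq + t$i, tkey)
  pos_b <- lapply(seq_along(bi),
                  function(s) match((bj[[s]] - 1) * neq + bi[[s]], tkey))
  list(D1 = D1, D2 = D2, y1 = y1, y2 = y2, nlit = nlit, m = m, p = p,
       c1 = c1, c2 = c2, nb = nb, neq = neq, Tm = Tm, nnz = length(Tm@x),
       p11 = pos(t11), x11 = t11$x, p22 = pos(t22), x22 = t22$x,
       p12 = pos(t12), x12 = t12$x, pos_b = pos_b, bx = bx, blk = blk,
       ldA = ldA,
       y11 = sum(y1^2), y22 = sum(y2^2), y12 = sum(y1 * y2),
       D1ty1 = as.numeric(Matrix::crossprod(D1, y1)),
       D1ty2 = as.numeric(Matrix::crossprod(D1, y2)),
       D2ty1 = as.numeric(Matrix::crossprod(D2, y1)),
       D2ty2 = as.numeric(Matrix::crossprod(D2, y2)),
       labels1 = dm1$fixed_labels, labels2 = dm2$fixed_labels,
       block_names = c(paste0(names(dm1$Zlist), "_t1"), "dam_ls"))
}

.biv_m2ll <- function(ws, G, R2) {
  ldG <- determinant(G, logarithm = TRUE)
  ldR <- determinant(R2, logarithm = TRUE)
  if (ldG$sign <= 0 || ldR$sign <= 0) return(1e12)
  if (rcond(G) < 1e-12 || rcond(R2) < 1e-12) return(1e12)
  Ginv <- solve(G)
  Rinv <- solve(R2)
  xv <- numeric(ws$nnz)
  xv[ws$p11] <- Rinv[1, 1] * ws$x11
  xv[ws$p22] <- xv[ws$p22] + Rinv[2, 2] * ws$x22
  xv[ws$p12] <- xv[ws$p12] + Rinv[1, 2] * ws$x12
  for (s in seq_along(ws$pos_b)) {
    kl <- ws$blk[[s]]
    xv[ws$pos_b[[s]]] <- xv[ws$pos_b[[s]]] + Ginv[kl[1], kl[2]] * ws$bx[[s]]
  }
  C <- ws$Tm
  C@x <- xv
  Ch <- tryCatch(suppressWarnings(
    Matrix::Cholesky(C, LDL = FALSE, super = TRUE, perm = TRUE)),
    error = function(e) NULL)
  if (is.null(Ch)) return(1e12)
  # RHS: D1'(r11 y1 + r12 y2) + D2'(r12 y1 + r22 y2); D1, D2 already live
  # in the common column space, so the two contributions add.
  Wty <- (Rinv[1, 1] * ws$D1ty1 + Rinv[1, 2] * ws$D1ty2) +
    (Rinv[1, 2] * ws$D2ty1 + Rinv[2, 2] * ws$D2ty2)
  s <- .dvec(Matrix::solve(Ch, Wty, system = "A"))
  yRy <- Rinv[1, 1] * ws$y11 + 2 * Rinv[1, 2] * ws$y12 + Rinv[2, 2] * ws$y22
  quad <- yRy - sum(s * Wty)
  if (!is.finite(quad) || quad <= 0) return(1e12)
  ldC <- 2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus)
  n_obs <- 2 * ws$nlit
  val <- ws$nlit * as.numeric(ldR$modulus) +
    ws$m * as.numeric(ldG$modulus) + ws$nb * ws$ldA + ldC + quad +
    (n_obs - ws$p) * .LOG2PI
  attr(val, "sol") <- s
  val
}

.theta_to_psd <- function(theta, k) {
  L <- matrix(0, k, k)
  pos <- 1L
  for (j in seq_len(k)) {
    L[j, j] <- exp(pmin(pmax(theta[pos], -23), 23))
    pos <- pos + 1L
    if (j < k) {
      L[(j + 1L):k, j] <- theta[pos:(pos + k - j - 1L)]
      pos <- pos + (k - j)
    }
  }
  L %*% t(L)
}

.psd_to_theta <- function(M) {
  L <- t(chol(M))
  k <- nrow(M)
  th <- numeric(0)
  for (j in seq_len(k)) {
    th <- c(th, log(L[j, j]))
    if (j < k) th <- c(th, L[(j + 1L):k, j])
  }
  th
}

#' Bivariate litter weight / litter size model
#'
#' Joint REML fit of total litter weight (trait 1, under the random
#' regression structure or one of the traditional variants) and litter size
#' (trait 2, dam intercept animal model). The two records of a litter share
#' an estimated 2x2 residual covariance; the genetic covariance matrix
#' spans the trait-1 random blocks plus the dam effect for litter size.
#' Reports the genetic correlation between the dam effect on litter weight
#' and the breeding value for litter size.
#'
#' @param litters litter records.
#' @param ped an [pedigree()].
#' @param variant treatment of trait 1: `"RRM"` (dam and sire slopes),
#'   `"TLW"`, `"LWA"` or `"ABW"` (dam intercept effect).
#' @param n_max litter-size scaling maximum.
#' @param age_poly_order fixed Legendre age curve order for trait 1.
#' @param ls_fixed_age also put the age curve on the litter-size trait?
#'   Default `FALSE`: generation effects only.
#' @param se compute standard errors (numerical information matrix)?
#' @param control a [rrm_control()]; `maxit`/`reltol`/`verbose` are used.
#' @return object of class `rrm_bivfit` with `G` (genetic covariance),
#'   `R2`, `loglik`, `correlations` and optional `se` tables.
#' @export
fit_bivariate_lw_ls <- function(litters, ped, variant = c("RRM", "TLW",
                                                          "LWA", "ABW"),
                                n_max = NULL, age_poly_order = 2,
                                ls_fixed_age = FALSE, se = TRUE,
                                control = rrm_control()) {
  variant <- match.arg(variant)
  litters <- validate_litters(litters)
  if (stats::sd(litters$litter_size) < 1e-12 ||
      stats::sd(litters$litter_weight_g - litters$litter_size) < 1e-12)
    stop("degenerate traits: litter size and weight must carry ",
         "independent variation")
  ws <- .biv_prep(litters, ped, variant, n_max, age_poly_order, ls_fixed_age)
  nb <- ws$nb

  # starting values from univariate fits
  uni1 <- rrm_fit(litters, ped, variant = variant, n_max = n_max,
                  age_poly_order = age_poly_order,
                  include_sire = (variant == "RRM"),
                  control = rrm_control(se = FALSE, pev = FALSE))
  lit2 <- litters
  lit2$litter_weight_g <- as.numeric(litters$litter_size)
  uni2 <- rrm_fit(lit2, ped, variant = "TLW", n_max = n_max,
                  age_poly_order = if (ls_fixed_age) age_poly_order else 0,
                  include_sire = FALSE,
                  control = rrm_control(se = FALSE, pev = FALSE))
  G0 <- diag(c(diag(uni1$G), uni2$G[1, 1]), nb)
  if (nb == 3) G0[1, 2] <- G0[2, 1] <- uni1$G[1, 2]
  R0 <- diag(c(uni1$sigma_e2, uni2$sigma_e2), 2)
  # small cross terms keep the Cholesky parameterization away from zero
  G0 <- G0 + diag(1e-3 * diag(G0))
  theta0 <- c(.psd_to_theta(G0), .psd_to_theta(R0))
  nG <- nb * (nb + 1) / 2
  evals <- 0L
  obj <- function(theta) {
    evals <<- evals + 1L
    G <- .theta_to_psd(theta[seq_len(nG)], nb)
    R2 <- .theta_to_psd(theta[nG + 1:3], 2)
    as.numeric(.biv_m2ll(ws, G, R2))
  }
  # coarse simplex search followed by a quasi-Newton polish
  op <- stats::optim(theta0, obj, method = "Nelder-Mead",
                     control = list(maxit = max(control$maxit, 600),
                                    reltol = 1e-7))
  op <- stats::optim(op$par, obj, method = "BFGS",
                     control = list(maxit = 150, reltol = 1e-12))
  theta <- op$par
  G <- .theta_to_psd(theta[seq_len(nG)], nb)
  R2 <- .theta_to_psd(theta[nG + 1:3], 2)
  dimnames(G) <- list(ws$block_names, ws$block_names)
  dimnames(R2) <- list(c("lw", "ls"), c("lw", "ls"))
  val <- .biv_m2ll(ws, G, R2)
  sol <- attr(val, "sol")
  loglik <- -0.5 * as.numeric(val)

  k_ls <- nb
  r_dam_ls <- G[1, k_ls] / sqrt(G[1, 1] * G[k_ls, k_ls])
  correlations <- c(r_dam_t1_ls = r_dam_ls)
  if (nb == 3) {
    correlations <- c(correlations,
                      r_sire_t1_ls = G[2, 3] / sqrt(G[2, 2] * G[3, 3]),
                      r_dam_sire_t1 = G[1, 2] / sqrt(G[1, 1] * G[2, 2]))
  }

  se_tab <- NULL
  if (se) {
    # numerical observed-information standard errors on the natural scale
    natural <- c(G[upper.tri(G, diag = TRUE)], R2[upper.tri(R2, diag = TRUE)])
    idxG <- which(upper.tri(G, diag = TRUE), arr.ind = TRUE)
    f_nat <- function(v) {
      Gn <- G; Rn <- R2
      Gn[upper.tri(Gn, diag = TRUE)] <- v[seq_len(nG)]
      Gn[lower.tri(Gn)] <- t(Gn)[lower.tri(Gn)]
      Rn[upper.tri(Rn, diag = TRUE)] <- v[nG + 1:3]
      Rn[lower.tri(Rn)] <- t(Rn)[lower.tri(Rn)]
      as.numeric(.biv_m2ll(ws, Gn, Rn))
    }
    steps <- pmax(0.05 * abs(natural), 0.01)
    H <- tryCatch(stats::optimHess(natural, f_nat,
                                   control = list(ndeps = steps)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      H <- (H + t(H)) / 2
      ev <- eigen(H, symmetric = TRUE)
      if (any(ev$values <= 0)) H <- NULL  # off-optimum curvature; no SEs
      V <- if (is.null(H)) NULL else
        tryCatch(solve(H / 2), error = function(e) NULL)
      if (!is.null(V)) {
        se_vals <- sqrt(pmax(diag(V), 0))
        se_tab <- list(G_se = se_vals[seq_len(nG)], R2_se = se_vals[nG + 1:3],
                       vcov = V)
        # delta-method SE for the dam(t1)-LS genetic correlation
        iG <- function(r, c) which(idxG[, 1] == min(r, c) &
                                     idxG[, 2] == max(r, c))
        g <- numeric(length(natural))
        g[iG(1, 1)] <- -r_dam_ls / (2 * G[1, 1])
        g[iG(k_ls, k_ls)] <- -r_dam_ls / (2 * G[k_ls, k_ls])
        g[iG(1, k_ls)] <- 1 / sqrt(G[1, 1] * G[k_ls, k_ls])
        se_tab$r_dam_t1_ls_se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
      }
    }
  }
  structure(list(G = G, R2 = R2, loglik = loglik,
                 correlations = correlations, se = se_tab,
                 converged = op$convergence == 0L, evals = evals,
                 variant = variant, nlit = ws$nlit, m = ws$m,
                 fixed = stats::setNames(
                   sol[seq_len(ws$p)],
                   c(paste0("lw:", ws$labels1), paste0("ls:", ws$labels2))),
                 u = sol[-seq_len(ws$p)]),
            class = "rrm_bivfit")
}

#' @export
print.rrm_bivfit <- function(x, ...) {
  cat("Bivariate litter weight (", x$variant, ") / litter size model\n",
      sep = "")
  cat(sprintf("  %d litters (%d records), %d animals; REML log-likelihood %.4f (%s)\n",
              x$nlit, 2 * x$nlit, x$m, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat("  Genetic covariance G:\n")
  print(round(x$G, 4))
  cat("  Residual covariance R2:\n")
  print(round(x$R2, 4))
  cat("  Genetic correlations:\n")
  print(round(x$correlations, 3))
  if (!is.null(x$se) && !is.null(x$se$r_dam_t1_ls_se))
    cat(sprintf("  se[r(dam LW, LS)] = %.3f\n", x$se$r_dam_t1_ls_se))
  invisible(x)
}
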