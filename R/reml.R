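# REML engine for the litter-weight random regression model.
#
# The mixed model is y = X b + sum_k Z_k u_k + e with
# var(u) = G (x) A (Kronecker), var(e) = I sigma_e^2. The restricted
# likelihood is evaluated through Henderson's mixed-model equations with a
# cached sparse Cholesky factorization: writing Gamma = G / sigma_e^2 and
# C = W'W + Gamma^{-1} (x) A^{-1} (W = [X Z]),
#
#   -2 l_R = (n-p) log sigma_e^2 + m log|Gamma| + b log|A| + log|C|
#            + (y'y - s'W'y)/sigma_e^2 + (n-p) log 2 pi,
#
# where s solves C s = W'y, p = rank(X), m = animals, b = random blocks.
# sigma_e^2 profiles out analytically, leaving a b(b+1)/2-dimensional
# maximization over the Cholesky factor of Gamma.

.LOG2PI <- log(2 * pi)

# strip a dense Matrix vector result to a plain numeric without the slow
# S4 coercion path
.dvec <- function(v) if (is.numeric(v)) v else v@x

#' Control parameters for REML fitting
#'
#' @param maxit maximum number of likelihood evaluations in the
#'   derivative-free search.
#' @param reltol relative convergence tolerance on -2 log-likelihood.
#' @param se compute average-information standard errors at convergence?
#' @param pev compute prediction error variances / reliabilities (exact
#'   inverse, only when the system has at most `pev_cap` equations)?
#' @param pev_cap equation-count cap for the exact MME inverse.
#' @param init optional list with starting values `sigma_t2`, `sigma_s2`,
#'   `sigma_ts`, `sigma_e2` (absolute, same scale as the data).
#' @param warm_start initialize the two-block search from a cheap dam-only
#'   fit (ignored when `init` is given)?
#' @param verbose print iteration-level progress?
#' @return a list of class `rrm_control`.
#' @export
rrm_control <- function(maxit = 400, reltol = 1e-9, se = TRUE, pev = TRUE,
                        pev_cap = 5000, init = NULL, warm_start = TRUE,
                        verbose = FALSE) {
  structure(list(maxit = maxit, reltol = reltol, se = se, pev = pev,
                 pev_cap = pev_cap, init = init, warm_start = warm_start,
                 verbose = verbose),
            class = "rrm_control")
}

# ---- sparse MME workspace -------------------------------------------------

# Precomputes the sparse pattern of C = W'W + Gamma^{-1} (x) A^{-1} and
# index maps so that each likelihood evaluation is a numeric fill plus a
# Cholesky refactorization with cached symbolic analysis.
.mme_prep <- function(dm, ainv) {
  X <- dm$X
  Zl <- dm$Zlist
  nb <- length(Zl)
  m <- dm$m
  p <- ncol(X)
  W <- do.call(cbind, c(list(X), unname(Zl)))
  y <- dm$y
  n <- length(y)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y^2)

  ut <- as(as(WtW, "generalMatrix"), "TsparseMatrix")
  keepw <- ut@i <= ut@j
  wi <- ut@i[keepw] + 1L
  wj <- ut@j[keepw] + 1L
  wx <- ut@x[keepw]

  at <- as(as(ainv, "generalMatrix"), "TsparseMatrix")
  ai <- at@i + 1L
  aj <- at@j + 1L
  ax <- at@x
  upper <- ai <= aj

  bi <- list(); bj <- list(); bx <- list(); blk <- list()
  for (k in seq_len(nb)) for (l in k:nb) {
    if (k == l) {
      ii <- p + (k - 1L) * m + ai[upper]
      jj <- p + (l - 1L) * m + aj[upper]
      xx <- ax[upper]
    } else {
      ii <- p + (k - 1L) * m + ai
      jj <- p + (l - 1L) * m + aj
      xx <- ax
    }
    bi <- c(bi, list(ii)); bj <- c(bj, list(jj)); bx <- c(bx, list(xx))
    blk <- c(blk, list(c(k, l)))
  }
  neq <- p + nb * m
  Tm <- Matrix::sparseMatrix(i = c(wi, unlist(bi)), j = c(wj, unlist(bj)),
                             x = c(wx, unlist(bx)), dims = c(neq, neq),
                             symmetric = TRUE)
  tkey <- (rep(seq_len(neq), diff(Tm@p)) - 1) * neq + Tm@i + 1
  pos_w <- match((wj - 1) * neq + wi, tkey)
  pos_b <- lapply(seq_along(bi),
                  function(s) match((bj[[s]] - 1) * neq + bi[[s]], tkey))
  list(W = W, y = y, n = n, p = p, m = m, nb = nb, neq = neq,
       Wty = Wty, yty = yty, Tm = Tm, nnz = length(Tm@x),
       pos_w = pos_w, wx = wx, pos_b = pos_b, bx = bx, blk = blk,
       ldA = attr(ainv, "logdet"), Zlist = Zl, X = X,
       ainv = ainv)
}

# Fill C for a given Gamma^{-1} and return its Cholesky factor. A fresh
# supernodal factorization beats a cached-symbolic simplicial update by an
# order of magnitude on pedigree-structured systems.
.mme_factor <- function(ws, Ginv) {
  xv <- numeric(ws$nnz)
  xv[ws$pos_w] <- ws$wx
  for (s in seq_along(ws$pos_b)) {
    kl <- ws$blk[[s]]
    xv[ws$pos_b[[s]]] <- xv[ws$pos_b[[s]]] + Ginv[kl[1], kl[2]] * ws$bx[[s]]
  }
  C <- ws$Tm
  C@x <- xv
  suppressWarnings(Matrix::Cholesky(C, LDL = FALSE, super = TRUE,
                                    perm = TRUE))
}

# Profiled -2 restricted log-likelihood at Gamma = G/sigma_e2. Returns the
# value with attributes used at convergence.
.mme_profile_m2ll <- function(ws, Gamma) {
  ldg <- determinant(Gamma, logarithm = TRUE)
  if (ldg$sign <= 0) return(1e12)
  if (nrow(Gamma) > 1L && rcond(Gamma) < 1e-14) return(1e12)
  Ginv <- solve(Gamma)
  Ch <- tryCatch(.mme_factor(ws, Ginv), error = function(e) NULL)
  if (is.null(Ch)) return(1e12)
  ldC <- 2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus)
  s <- .dvec(Matrix::solve(Ch, ws$Wty, system = "A"))
  quad <- ws$yty - sum(s * ws$Wty)
  if (!is.finite(quad) || quad <= 0) return(1e12)
  np <- ws$n - ws$p
  sigma_e2 <- quad / np
  val <- np * log(sigma_e2) + ws$m * as.numeric(ldg$modulus) +
    ws$nb * ws$ldA + ldC + np * (1 + .LOG2PI)
  if (!is.finite(val)) return(1e12)
  attr(val, "sigma_e2") <- sigma_e2
  attr(val, "sol") <- s
  attr(val, "Ch") <- Ch
  val
}

# -2 restricted log-likelihood at fixed (G, sigma_e2), sparse MME path.
.mme_m2ll_at <- function(ws, G, sigma_e2) {
  G <- as.matrix(G)
  Gamma <- G / sigma_e2
  ldg <- determinant(Gamma, logarithm = TRUE)
  if (ldg$sign <= 0) stop("G must be positive definite")
  Ch <- .mme_factor(ws, solve(Gamma))
  ldC <- 2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus)
  s <- .dvec(Matrix::solve(Ch, ws$Wty, system = "A"))
  quad <- ws$yty - sum(s * ws$Wty)
  np <- ws$n - ws$p
  np * log(sigma_e2) + ws$m * as.numeric(ldg$modulus) + ws$nb * ws$ldA +
    ldC + quad / sigma_e2 + np * .LOG2PI
}

.chol_to_gamma <- function(theta, nb) {
  L <- matrix(0, nb, nb)
  if (nb == 1L) {
    L[1, 1] <- exp(pmin(pmax(theta[1], -23), 23))
  } else {
    L[1, 1] <- exp(pmin(pmax(theta[1], -23), 23))
    L[2, 1] <- theta[2]
    L[2, 2] <- exp(pmin(pmax(theta[3], -23), 23))
  }
  L %*% t(L)
}

# ---- average information matrix ------------------------------------------

# AI_ij = 0.5 * (V_i P y)' P (V_j P y) for the variance parameters; V is
# linear in each parameter so the derivative matrices V_i are fixed.
# Returns the AI matrix in the order (vech(G) by blocks, sigma_e2).
.ai_matrix <- function(ws, Ch, sol, sigma_e2, ainv_ch) {
  y <- ws$y
  W <- ws$W
  Py <- (y - .dvec(W %*% sol)) / sigma_e2
  Amult <- function(v) .dvec(Matrix::solve(ainv_ch, v, system = "A"))
  Zw <- lapply(ws$Zlist, function(Z) .dvec(Matrix::crossprod(Z, Py)))
  AZw <- lapply(Zw, Amult)
  tvecs <- list()
  labs <- character(0)
  nb <- ws$nb
  bn <- names(ws$Zlist)
  for (k in seq_len(nb)) for (l in k:nb) {
    v <- .dvec(ws$Zlist[[k]] %*% AZw[[l]])
    if (l != k) v <- v + .dvec(ws$Zlist[[l]] %*% AZw[[k]])
    tvecs <- c(tvecs, list(v))
    labs <- c(labs, if (k == l) paste0("sigma2_", bn[k])
              else paste0("cov_", bn[k], "_", bn[l]))
  }
  tvecs <- c(tvecs, list(Py))
  labs <- c(labs, "sigma2_e")
  Pt <- lapply(tvecs, function(v) {
    sv <- .dvec(Matrix::solve(Ch, .dvec(Matrix::crossprod(W, v)),
                               system = "A"))
    (v - .dvec(W %*% sv)) / sigma_e2
  })
  q <- length(tvecs)
  AI <- matrix(0, q, q, dimnames = list(labs, labs))
  for (i in seq_len(q)) for (j in i:q) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(tvecs[[i]] * Pt[[j]])
  }
  AI
}

# ---- main fitting function ------------------------------------------------

#' Fit the litter-weight model by REML
#'
#' Estimates the parental-slope genetic (co)variance components and the
#' residual variance of the random regression model for total litter weight
#' (or of one of the traditional baseline variants) by restricted maximum
#' likelihood, using a pedigree-based animal model. Returns breeding-value
#' (BLUP) estimates of the dam and sire effects with prediction error
#' variances and reliabilities.
#'
#' The restricted likelihood is maximized by a derivative-free search over
#' the Cholesky factor of G/sigma_e^2 (residual variance profiled out);
#' standard errors come from the inverse average-information matrix
#' evaluated at the optimum.
#'
#' @param litters litter records (see [read_litters()] for the schema).
#' @param ped an [pedigree()] covering all dams and sires.
#' @param variant `"RRM"` (random slopes on standardized litter size,
#'   default), or a baseline: `"TLW"`, `"LWA"`, `"ABW"`.
#' @param include_sire include the random sire block? Setting `FALSE` gives
#'   the reduced (dam-only) model of the sire likelihood-ratio test.
#' @param n_max scaling maximum for litter size; default: max observed.
#' @param age_poly_order order of the fixed Legendre mating-age curve.
#' @param age_range optional standardization interval for mating age.
#' @param control a [rrm_control()] list.
#' @return an object of class `rrm_fit`; see [summary.rrm_fit()],
#'   [ranef.rrm_fit()], [heritability()].
#' @examples
#' cfg <- sim_config(n_generations = 4, pairs_per_generation = 30, seed = 1)
#' sim <- simulate_dataset(cfg)
#' fit <- rrm_fit(sim$litters, sim$pedigree,
#'                control = rrm_control(se = FALSE, pev = FALSE))
#' fit
#' @export
rrm_fit <- function(litters, ped, variant = c("RRM", "TLW", "LWA", "ABW"),
                    include_sire = TRUE, n_max = NULL, age_poly_order = 2,
                    age_range = NULL, control = rrm_control()) {
  variant <- match.arg(variant)
  dm <- build_design(litters, ped, variant = variant, n_max = n_max,
                     age_poly_order = age_poly_order, age_range = age_range,
                     include_sire = include_sire)
  ainv <- a_inverse(ped)
  fit <- .rrm_fit_design(dm, ainv, control)
  fit$ped <- ped
  fit$call <- match.call()
  fit
}

.rrm_fit_design <- function(dm, ainv, control = rrm_control()) {
  ws <- .mme_prep(dm, ainv)
  nb <- ws$nb
  vy <- stats::var(ws$y)
  init <- control$init
  if (is.null(init) && nb == 2 && control$warm_start) {
    # one-dimensional dam-only profile fit provides sigma_t2/sigma_e2
    dm1 <- dm
    dm1$Zlist <- dm$Zlist[1]
    ws1 <- .mme_prep(dm1, ainv)
    op1 <- stats::optimize(function(t)
      as.numeric(.mme_profile_m2ll(ws1, matrix(exp(t), 1, 1))),
      interval = c(-18, 12), tol = 1e-6)
    v1 <- .mme_profile_m2ll(ws1, matrix(exp(op1$minimum), 1, 1))
    se2_0 <- attr(v1, "sigma_e2")
    st_0 <- exp(op1$minimum) * se2_0
    init <- list(sigma_e2 = se2_0, sigma_t2 = st_0,
                 sigma_s2 = 0.1 * st_0, sigma_ts = 0.02 * st_0)
  }
  if (is.null(init)) {
    init <- list(sigma_e2 = 0.5 * vy, sigma_t2 = 0.4 * vy,
                 sigma_s2 = 0.1 * vy, sigma_ts = 0)
  }
  Gamma0 <- if (nb == 2) {
    matrix(c(init$sigma_t2, init$sigma_ts, init$sigma_ts,
             max(init$sigma_s2, 1e-4 * vy)), 2, 2) / init$sigma_e2
  } else {
    matrix(init$sigma_t2 / init$sigma_e2, 1, 1)
  }
  L0 <- t(chol(Gamma0))
  evals <- 0L
  obj <- function(theta) {
    evals <<- evals + 1L
    Gamma <- .chol_to_gamma(theta, nb)
    v <- as.numeric(.mme_profile_m2ll(ws, Gamma))
    if (control$verbose) message(sprintf("eval %d: -2l = %.6f", evals, v))
    v
  }
  if (nb == 1L) {
    op <- stats::optimize(function(t) obj(t), interval = c(-18, 12),
                          tol = 1e-8)
    theta_hat <- op$minimum
    converged <- TRUE
  } else {
    theta0 <- c(log(L0[1, 1]), L0[2, 1], log(max(L0[2, 2], 1e-8)))
    op <- stats::optim(theta0, obj, method = "Nelder-Mead",
                       control = list(maxit = control$maxit,
                                      reltol = control$reltol))
    theta_hat <- op$par
    converged <- op$convergence == 0L
    # the nested dam-only model bounds the full model from below; if the
    # simplex ended under that bound (a boundary-hugging run), restart once
    # from the reduced solution with a vanishing sire block
    if (exists("op1", inherits = FALSE)) {
      gap <- op$value - (as.numeric(v1) - 1e-8)
      if (gap > 0) {
        g1 <- init$sigma_t2 / init$sigma_e2
        th_red <- c(0.5 * log(g1), 0, 0.5 * log(1e-4 * g1))
        op_b <- stats::optim(th_red, obj, method = "Nelder-Mead",
                             control = list(maxit = control$maxit,
                                            reltol = control$reltol))
        if (op_b$value < op$value) {
          op <- op_b
          theta_hat <- op$par
          converged <- op$convergence == 0L
        }
      }
    }
  }
  Gamma <- .chol_to_gamma(theta_hat, nb)
  val <- .mme_profile_m2ll(ws, Gamma)
  sigma_e2 <- attr(val, "sigma_e2")
  sol <- attr(val, "sol")
  Ch <- attr(val, "Ch")
  G <- Gamma * sigma_e2
  bn <- names(dm$Zlist)
  dimnames(G) <- list(bn, bn)
  loglik <- -0.5 * as.numeric(val)

  p <- ws$p; m <- ws$m
  beta <- sol[seq_len(p)]
  names(beta) <- dm$fixed_labels
  ublocks <- lapply(seq_len(nb), function(k) sol[p + (k - 1L) * m + seq_len(m)])
  names(ublocks) <- bn

  boundary <- nb == 2 && G[2, 2] < 1e-6 * vy

  se <- rep(NA_real_, nb * (nb + 1) / 2 + 1)
  vcov_vc <- NULL
  ainv_ch <- Matrix::Cholesky(ainv, LDL = FALSE, perm = TRUE)
  if (control$se) {
    AI <- tryCatch(.ai_matrix(ws, Ch, sol, sigma_e2, ainv_ch),
                   error = function(e) NULL)
    if (!is.null(AI)) {
      vcov_vc <- tryCatch(solve(AI), error = function(e) NULL)
      if (!is.null(vcov_vc)) se <- sqrt(pmax(diag(vcov_vc), 0))
    }
  }

  # variance components in reporting order
  if (nb == 2) {
    vc <- c(sigma_t2 = G[1, 1], sigma_s2 = G[2, 2], sigma_ts = G[1, 2],
            sigma_e2 = sigma_e2)
    se <- unname(se)
    se_named <- c(sigma_t2 = se[1], sigma_s2 = se[3], sigma_ts = se[2],
                  sigma_e2 = se[4])
    # AI order was (sigma2_dam, cov_dam_sire, sigma2_sire, sigma2_e)
    corr_ts <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
    corr_ts_se <- NA_real_
    if (!is.null(vcov_vc)) {
      gvec <- c(-corr_ts / (2 * G[1, 1]),           # d r / d sigma_t2
                1 / sqrt(G[1, 1] * G[2, 2]),        # d r / d sigma_ts
                -corr_ts / (2 * G[2, 2]))           # d r / d sigma_s2
      Vsub <- vcov_vc[1:3, 1:3]
      corr_ts_se <- sqrt(max(drop(t(gvec) %*% Vsub %*% gvec), 0))
    }
  } else {
    vc <- c(sigma_t2 = G[1, 1], sigma_e2 = sigma_e2)
    se <- unname(se)
    se_named <- c(sigma_t2 = se[1], sigma_e2 = se[2])
    corr_ts <- NA_real_
    corr_ts_se <- NA_real_
  }

  blup <- NULL
  if (control$pev && ws$neq <= control$pev_cap) {
    CI <- Matrix::solve(Ch, system = "A")
    dC <- Matrix::diag(CI)
    pev <- lapply(seq_len(nb), function(k)
      sigma_e2 * dC[p + (k - 1L) * m + seq_len(m)])
    rel <- lapply(seq_len(nb), function(k) {
      pv <- G[k, k]
      if (pv <= 1e-12) return(rep(NA_real_, m))
      pmin(pmax(1 - pev[[k]] / pv, 0), 1)
    })
    blup <- data.frame(animal = dm$ped_ids %||% seq_len(m))
    blup$a_d <- ublocks[[1]]
    blup$pev_d <- pev[[1]]
    blup$rel_d <- rel[[1]]
    if (nb == 2) {
      blup$a_s <- ublocks[[2]]
      blup$pev_s <- pev[[2]]
      blup$rel_s <- rel[[2]]
    }
  }

  structure(list(
    varcomp = as.list(vc), se = as.list(se_named),
    G = G, sigma_e2 = sigma_e2,
    corr_ts = corr_ts, corr_ts_se = corr_ts_se,
    vcov_varcomp = vcov_vc,
    loglik = loglik, fixed = beta, u = ublocks, blup = blup,
    converged = converged, evals = evals, boundary = boundary,
    variant = dm$variant, include_sire = nb == 2, n_max = dm$n_max,
    nlit = ws$n, p = p, m = m,
    fingerprint = c(n = ws$n, sy = sum(ws$y), syy = ws$yty),
    design = dm
  ), class = "rrm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BLUP, prediction error variance and reliability at fixed components
#'
#' Solves the mixed-model equations at user-supplied variance components
#' (no REML step) and returns per-animal effect estimates, prediction error
#' variances from the exact inverse of the coefficient matrix, and
#' reliabilities 1 - PEV / sigma^2. Useful for studying how the
#' information content of a litter changes with its size.
#'
#' @param litters litter records.
#' @param ped an [pedigree()].
#' @param G genetic covariance at x = 1: scalar / 1x1 (dam only) or 2x2
#'   (dam + sire).
#' @param sigma_e2 residual variance.
#' @param variant design variant, as in [build_design()].
#' @param n_max litter-size scaling maximum.
#' @return data.frame with `animal`, `a_d`, `pev_d`, `rel_d` and the sire
#'   analogues when `G` is 2x2 (sire reliabilities are `NA` when the sire
#'   variance is zero).
#' @export
mme_blup <- function(litters, ped, G, sigma_e2, variant = "RRM",
                     n_max = NULL) {
  G <- as.matrix(G)
  nb <- nrow(G)
  stopifnot(nb %in% 1:2, sigma_e2 > 0)
  dm <- build_design(litters, ped, variant = variant, n_max = n_max,
                     include_sire = nb == 2)
  ainv <- a_inverse(ped)
  ws <- .mme_prep(dm, ainv)
  Gamma <- G / sigma_e2
  Ch <- .mme_factor(ws, solve(Gamma))
  sol <- .dvec(Matrix::solve(Ch, ws$Wty, system = "A"))
  CI <- Matrix::solve(Ch, system = "A")
  dC <- Matrix::diag(CI)
  p <- ws$p; m <- ws$m
  out <- data.frame(animal = ped$id,
                    a_d = sol[p + seq_len(m)],
                    pev_d = sigma_e2 * dC[p + seq_len(m)])
  out$rel_d <- pmin(pmax(1 - out$pev_d / G[1, 1], 0), 1)
  if (nb == 2) {
    out$a_s <- sol[p + m + seq_len(m)]
    out$pev_s <- sigma_e2 * dC[p + m + seq_len(m)]
    out$rel_s <- if (G[2, 2] > 1e-12)
      pmin(pmax(1 - out$pev_s / G[2, 2], 0), 1) else NA_real_
  }
  out
}

# ---- likelihood oracles ---------------------------------------------------

#' Restricted log-likelihood via the sparse MME path
#'
#' Evaluates the restricted log-likelihood at fixed variance components
#' using the same sparse mixed-model-equation identities as the fitter.
#'
#' @param dm a design from [build_design()].
#' @param G random-effect (co)variance matrix at x = 1 (b x b for b blocks).
#' @param sigma_e2 residual variance.
#' @param ainv sparse A-inverse from [a_inverse()].
#' @return the restricted log-likelihood (including all constants).
#' @export
reml_loglik <- function(dm, G, sigma_e2, ainv) {
  ws <- .mme_prep(dm, ainv)
  -0.5 * .mme_m2ll_at(ws, G, sigma_e2)
}

#' Restricted log-likelihood via the dense variance-matrix oracle
#'
#' Independent dense-path evaluation: builds V = Z (G (x) A) Z' + I
#' sigma_e^2 explicitly and computes
#' -2 l = log|V| + log|X'V^-1 X| + y'Py + (n - p) log 2 pi. Feasible for
#' small pedigrees only; used to cross-check the sparse path.
#'
#' @param dm a design from [build_design()].
#' @param G random-effect (co)variance matrix at x = 1.
#' @param sigma_e2 residual variance.
#' @param A dense numerator relationship matrix from [a_matrix()].
#' @return the restricted log-likelihood (same constants as
#'   [reml_loglik()]).
#' @export
reml_loglik_direct <- function(dm, G, sigma_e2, A) {
  G <- as.matrix(G)
  y <- dm$y
  n <- length(y)
  X <- as.matrix(dm$X)
  p <- qr(X)$rank
  Zl <- lapply(dm$Zlist, as.matrix)
  nb <- length(Zl)
  V <- diag(sigma_e2, n)
  for (k in seq_len(nb)) for (l in seq_len(nb)) {
    V <- V + G[k, l] * (Zl[[k]] %*% A %*% t(Zl[[l]]))
  }
  cV <- chol(V)
  ldV <- 2 * sum(log(diag(cV)))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  cX <- chol(XtViX)
  ldX <- 2 * sum(log(diag(cX)))
  XtViy <- crossprod(X, Vi_y)
  yPy <- sum(y * Vi_y) - drop(crossprod(XtViy, solve(XtViX, XtViy)))
  -0.5 * (ldV + ldX + yPy + (n - p) * .LOG2PI)
}

#' EM-REML for small systems
#'
#' Plain expectation-maximization REML updates computed with a dense
#' inverse of the mixed-model equations. Independent of the profiled
#' derivative-free fitter; intended for cross-checks on small pedigrees.
#'
#' @param dm a design from [build_design()].
#' @param ainv sparse A-inverse from [a_inverse()].
#' @param init optional list(G, sigma_e2) starting values.
#' @param maxit,tol iteration cap and -2 log-likelihood change tolerance.
#' @return list with `G`, `sigma_e2`, `loglik`, `iterations`, `converged`.
#' @export
reml_fit_em <- function(dm, ainv, init = NULL, maxit = 5000, tol = 1e-10) {
  ws <- .mme_prep(dm, ainv)
  nb <- ws$nb
  m <- ws$m
  p <- ws$p
  if (ws$neq > 4000) stop("EM-REML path is dense; system too large")
  vy <- stats::var(ws$y)
  if (is.null(init)) {
    G <- diag(c(0.4, 0.1)[seq_len(nb)] * vy, nb)
    sigma_e2 <- 0.5 * vy
  } else {
    G <- as.matrix(init$G)
    sigma_e2 <- init$sigma_e2
  }
  Ainv_d <- as.matrix(ainv)
  W <- as.matrix(ws$W)
  WtW <- crossprod(W)
  Wty <- ws$Wty
  old <- Inf
  converged <- FALSE
  it <- 0
  for (it in seq_len(maxit)) {
    Ginv <- solve(G)
    Cf <- WtW / sigma_e2
    for (k in seq_len(nb)) for (l in seq_len(nb)) {
      rows <- p + (k - 1L) * m + seq_len(m)
      cls <- p + (l - 1L) * m + seq_len(m)
      Cf[rows, cls] <- Cf[rows, cls] + Ginv[k, l] * Ainv_d
    }
    Cinv <- solve(Cf)
    sol <- drop(Cinv %*% (Wty / sigma_e2))
    ub <- lapply(seq_len(nb), function(k) sol[p + (k - 1L) * m + seq_len(m)])
    Gn <- matrix(0, nb, nb)
    for (k in seq_len(nb)) for (l in seq_len(nb)) {
      rows <- p + (k - 1L) * m + seq_len(m)
      cls <- p + (l - 1L) * m + seq_len(m)
      Gn[k, l] <- (sum(ub[[k]] * (Ainv_d %*% ub[[l]])) +
                     sum(Ainv_d * Cinv[rows, cls])) / m
    }
    Gn <- (Gn + t(Gn)) / 2
    sigma_e2_n <- (ws$yty - sum(sol * Wty)) / (ws$n - p)
    G <- Gn
    sigma_e2 <- sigma_e2_n
    cur <- .mme_m2ll_at(ws, G, sigma_e2)
    if (abs(old - cur) < tol * (abs(cur) + 1)) { converged <- TRUE; break }
    old <- cur
  }
  list(G = G, sigma_e2 = sigma_e2, loglik = -0.5 * as.numeric(old),
       iterations = it, converged = converged)
}

# ---- methods --------------------------------------------------------------

#' @export
print.rrm_fit <- function(x, ...) {
  cat("Litter-weight animal model (", x$variant,
      if (x$include_sire) ", dam + sire random effects" else ", dam only",
      ")\n", sep = "")
  cat(sprintf("  %d litters, %d animals, %d fixed effects; n_max = %d\n",
              x$nlit, x$m, x$p, x$n_max))
  cat(sprintf("  REML log-likelihood: %.4f (%s, %d evaluations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$evals))
  vc <- unlist(x$varcomp)
  se <- unlist(x$se)
  cat("  Variance components (at x = 1):\n")
  for (nm in names(vc)) {
    cat(sprintf("    %-9s %10.4f  (se %s)\n", nm, vc[[nm]],
                ifelse(is.na(se[[nm]]), "NA", sprintf("%.4f", se[[nm]]))))
  }
  if (!is.na(x$corr_ts))
    cat(sprintf("    r_ts      %10.3f  (se %s)\n", x$corr_ts,
                ifelse(is.na(x$corr_ts_se), "NA",
                       sprintf("%.3f", x$corr_ts_se))))
  if (x$boundary) cat("  note: sire variance at boundary\n")
  invisible(x)
}

#' Summary of a fitted litter-weight model
#'
#' @param object an `rrm_fit`.
#' @param ... unused.
#' @return list of class `summary.rrm_fit` with the variance component
#'   table, the maternal-direct transformation (RRM fits with a sire
#'   effect), fixed effects and heritabilities at the mean litter size.
#' @export
summary.rrm_fit <- function(object, ...) {
  vc <- unlist(object$varcomp)
  se <- unlist(object$se)
  tab <- data.frame(estimate = vc, se = se)
  md <- NULL
  h2 <- NULL
  if (object$include_sire && object$variant == "RRM") {
    md <- maternal_direct_from_slope(object$varcomp$sigma_t2,
                                     object$varcomp$sigma_s2,
                                     object$varcomp$sigma_ts)
    nbar <- mean(object$design$n)
    h2 <- heritability_at_ls(object$varcomp$sigma_t2, object$varcomp$sigma_s2,
                             object$varcomp$sigma_e2, nbar, object$n_max)
  }
  structure(list(fit = object, varcomp = tab, maternal_direct = md,
                 h2_at_mean_ls = h2, mean_ls = mean(object$design$n)),
            class = "summary.rrm_fit")
}

#' @export
print.summary.rrm_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$maternal_direct)) {
    md <- x$maternal_direct
    cat(sprintf("  Maternal-direct scale: sigma_m2 = %.4f, sigma_d2 = %.4f, sigma_md = %.4f\n",
                md$sigma_m2, md$sigma_d2, md$sigma_md))
  }
  if (!is.null(x$h2_at_mean_ls)) {
    h <- x$h2_at_mean_ls
    cat(sprintf("  Heritability at mean LS (%.2f): dam %.3f, sire %.3f, total %.3f\n",
                x$mean_ls, h[["h2_dam"]], h[["h2_sire"]], h[["h2_tot"]]))
  }
  invisible(x)
}

#' @export
coef.rrm_fit <- function(object, ...) object$fixed

#' @export
logLik.rrm_fit <- function(object, ...) {
  k <- if (object$include_sire) 4 else 2
  structure(object$loglik, df = k, class = "logLik")
}

#' Random-effect predictions
#'
#' Generic extractor for BLUPs of random effects.
#' @param object a fitted model object.
#' @param ... passed on to methods.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @describeIn ranef per-animal dam (and sire) effect estimates with
#'   prediction error variance and reliability (when computed); also the
#'   maternal/direct breeding values recovered through the inverse slope
#'   transformation for RRM fits with a sire block.
#' @export
ranef.rrm_fit <- function(object, ...) {
  ped <- object$ped
  ids <- if (!is.null(ped)) ped$id else seq_len(object$m)
  out <- data.frame(animal = ids, a_d = object$u[[1]],
                    stringsAsFactors = FALSE)
  if (object$include_sire) {
    out$a_s <- object$u[[2]]
    eff <- maternal_direct_effects(out$a_d, out$a_s)
    out$m <- eff$m
    out$b <- eff$b
  }
  if (!is.null(object$blup)) {
    out$pev_d <- object$blup$pev_d
    out$rel_d <- object$blup$rel_d
    if (object$include_sire) {
      out$pev_s <- object$blup$pev_s
      out$rel_s <- object$blup$rel_s
    }
  }
  out
}

#' @export
fitted.rrm_fit <- function(object, ...) {
  dm <- object$design
  f <- as.numeric(dm$X %*% object$fixed)
  for (k in seq_along(dm$Zlist))
    f <- f + as.numeric(dm$Zlist[[k]] %*% object$u[[k]])
  f
}

#' @export
residuals.rrm_fit <- function(object, ...) {
  object$design$y - fitted(object)
}

#' @export
predict.rrm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  dm <- build_design(newdata, object$ped, variant = object$variant,
                     n_max = object$n_max,
                     age_poly_order = object$design$age_poly_order,
                     age_range = object$design$age_range,
                     include_sire = object$include_sire)
  if (!identical(dm$fixed_labels, object$design$fixed_labels))
    stop("newdata implies a different fixed-effect structure; ",
         "generation levels must match the fitted data")
  f <- as.numeric(dm$X %*% object$fixed)
  for (k in seq_along(dm$Zlist))
    f <- f + as.numeric(dm$Zlist[[k]] %*% object$u[[k]])
  f
}

#' @export
simulate.rrm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$ped))
    stop("fit carries no pedigree; cannot simulate genetic effects")
  dm <- object$design
  fx <- as.numeric(dm$X %*% object$fixed)
  G <- object$G
  out <- matrix(0, dm$nlit, nsim)
  for (r in seq_len(nsim)) {
    u <- simulate_breeding_values(object$ped, G)
    g <- as.numeric(dm$Zlist[[1]] %*% u[, 1])
    if (object$include_sire)
      g <- g + as.numeric(dm$Zlist[[2]] %*% u[, 2])
    out[, r] <- fx + g + stats::rnorm(dm$nlit, 0, sqrt(object$sigma_e2))
  }
  as.data.frame(out)
}

#' @export
plot.rrm_fit <- function(x, ...) {
  if (!(x$include_sire && x$variant == "RRM"))
    stop("plot is defined for RRM fits with a sire effect")
  n_grid <- seq_len(x$n_max)
  xx <- n_grid / x$n_max
  st <- x$varcomp$sigma_t2
  ss <- x$varcomp$sigma_s2
  se2 <- x$varcomp$sigma_e2
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(n_grid, cbind(xx^2 * (st + ss), xx^2 * st, xx^2 * ss),
                    type = "l", lty = 1:3, col = 1, xlab = "litter size",
                    ylab = "genetic variance (g²)")
  graphics::legend("topleft", c("total", "dam", "sire"), lty = 1:3, bty = "n")
  h <- t(vapply(n_grid, function(n)
    heritability_at_ls(st, ss, se2, n, x$n_max), numeric(3)))
  graphics::matplot(n_grid, h[, c(3, 1, 2)], type = "l", lty = 1:3, col = 1,
                    xlab = "litter size", ylab = "heritability", ylim = c(0, 1))
  graphics::legend("topleft", c("total", "dam", "sire"), lty = 1:3, bty = "n")
  invisible(x)
}
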