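#' Read litter records from CSV
#'
#' Expects a header with columns
#' `litter_id,dam,sire,generation,mating_age_days,litter_size,litter_weight_g`.
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame` of litter records.
#' @export
read_litters <- function(path) {
  if (!file.exists(path)) stop("litter file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_litters(df)
}

#' Validate litter records
#'
#' Checks column presence, positivity of litter size and weight, and basic
#' types. Used by [read_litters()] and the fitting entry points.
#'
#' @param litters a data.frame of litter records.
#' @return the validated data.frame (invisibly coerced column types).
#' @export
validate_litters <- function(litters) {
  need <- c("litter_id", "dam", "sire", "generation", "mating_age_days",
            "litter_size", "litter_weight_g")
  miss <- setdiff(need, names(litters))
  if (length(miss))
    stop("litter records lack column(s): ", paste(miss, collapse = ", "))
  litters$dam <- as.character(litters$dam)
  litters$sire <- as.character(litters$sire)
  litters$litter_size <- as.integer(litters$litter_size)
  if (any(litters$litter_size < 1L)) stop("litter_size must be >= 1")
  if (any(litters$litter_weight_g <= 0)) stop("litter_weight_g must be > 0")
  if (any(litters$mating_age_days <= 0)) stop("mating_age_days must be > 0")
  litters
}

#' Standardize litter size
#'
#' Maps a litter size n to x = n / n_max, so x lies in (0, 1] and the
#' genetic (co)variances of the random regression are expressed at the
#' maximum litter size (x = 1).
#'
#' @param n integer litter size(s), 1 <= n <= n_max.
#' @param n_max maximum litter size of the dataset.
#' @return numeric x in (0, 1].
#' @export
standardize_litter_size <- function(n, n_max) {
  if (any(n < 1)) stop("litter size must be >= 1")
  if (any(n > n_max)) stop("litter size exceeds n_max (", n_max, ")")
  n / n_max
}

#' Legendre polynomial covariates of mating age
#'
#' Linearly rescales age to s in [-1, 1] over `age_range` and evaluates the
#' Legendre polynomials P_1 .. P_order by the standard recurrence
#' (P1(s) = s, P2(s) = (3 s^2 - 1) / 2, ...). These form the fixed mating
#' age curve of the model; the constant P_0 is absorbed by the intercept.
#'
#' @param age numeric vector of dam mating ages (days).
#' @param age_range length-2 numeric, the (min, max) used for rescaling.
#' @param order highest polynomial order (>= 1), default 2.
#' @param out_of_range `"clamp"` (default, with a warning) or `"error"` for
#'   ages outside `age_range`.
#' @return matrix with `order` columns named `P1`, `P2`, ...
#' @export
legendre_age_covariates <- function(age, age_range, order = 2,
                                    out_of_range = c("clamp", "error")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2], order >= 1)
  out <- age < age_range[1] | age > age_range[2]
  if (any(out)) {
    if (out_of_range == "error")
      stop(sum(out), " age value(s) outside [", age_range[1], ", ",
           age_range[2], "]")
    warning(sum(out), " age value(s) clamped to the standardization range")
    age <- pmin(pmax(age, age_range[1]), age_range[2])
  }
  s <- 2 * (age - age_range[1]) / (age_range[2] - age_range[1]) - 1
  P <- matrix(0, length(s), order + 1L)
  P[, 1L] <- 1
  P[, 2L] <- s
  if (order >= 2) {
    for (k in 1:(order - 1L))
      P[, k + 2L] <- ((2 * k + 1) * s * P[, k + 1L] - k * P[, k]) / (k + 1)
  }
  P <- P[, -1L, drop = FALSE]
  colnames(P) <- paste0("P", seq_len(order))
  P
}

#' Build fixed and random design structures
#'
#' Assembles the response, the fixed-effect matrix X (generation classes
#' with reference coding, Legendre mating-age covariates, and a
#' litter-size covariate where the variant calls for one) and the random
#' incidence matrices of the dam and sire effects.
#'
#' Variants: `"RRM"` regresses total litter weight on dam and sire random
#' slopes in x = n/n_max (entries of Z are x) with a fixed covariate x;
#' `"TLW"` models total litter weight with a dam (and optionally sire)
#' intercept effect and no litter-size adjustment; `"LWA"` is TLW plus a
#' fixed linear regression on the raw litter size; `"ABW"` models average
#' birth weight per litter (y/n) with intercept random effects.
#'
#' @param litters validated litter records (see [validate_litters()]).
#' @param ped an [pedigree()] object covering all parents.
#' @param variant one of `"RRM"`, `"TLW"`, `"LWA"`, `"ABW"`.
#' @param n_max maximum litter size defining x; defaults to the maximum
#'   observed litter size.
#' @param age_poly_order order of the fixed Legendre age curve (0 disables).
#' @param age_range standardization interval; defaults to the observed range.
#' @param include_sire include the random sire effect block?
#' @return list of class `rrm_design` with elements `y`, `X` (sparse),
#'   `Zlist` (named list of sparse incidence matrices), `x`, `n`, `p`
#'   (rank of X), plus bookkeeping (`variant`, `n_max`, `dam_idx`,
#'   `sire_idx`, `fixed_labels`, `m` animals).
#' @export
build_design <- function(litters, ped, variant = c("RRM", "TLW", "LWA", "ABW"),
                         n_max = NULL, age_poly_order = 2, age_range = NULL,
                         include_sire = TRUE) {
  variant <- match.arg(variant)
  litters <- validate_litters(litters)
  stopifnot(inherits(ped, "rrm_pedigree"))
  dam_idx <- match(litters$dam, ped$id)
  sire_idx <- match(litters$sire, ped$id)
  if (anyNA(dam_idx))
    stop("dam id(s) not in pedigree: ",
         paste(utils::head(unique(litters$dam[is.na(dam_idx)]), 5), collapse = ", "))
  if (anyNA(sire_idx))
    stop("sire id(s) not in pedigree: ",
         paste(utils::head(unique(litters$sire[is.na(sire_idx)]), 5), collapse = ", "))
  nlit <- nrow(litters)
  m <- ped$n
  nvec <- litters$litter_size
  if (is.null(n_max)) n_max <- max(nvec)
  x <- standardize_litter_size(nvec, n_max)

  # fixed part: intercept + generation classes (reference coding) + age curve
  cols <- list(`(Intercept)` = rep(1, nlit))
  gf <- factor(litters$generation)
  if (nlevels(gf) > 1L) {
    gm <- stats::model.matrix(~ gf)[, -1L, drop = FALSE]
    colnames(gm) <- paste0("gen", levels(gf)[-1L])
    for (j in seq_len(ncol(gm))) cols[[colnames(gm)[j]]] <- gm[, j]
  }
  if (age_poly_order >= 1) {
    if (is.null(age_range)) age_range <- range(litters$mating_age_days)
    if (age_range[1] == age_range[2]) {
      age_range <- age_range + c(-0.5, 0.5)
    }
    P <- legendre_age_covariates(litters$mating_age_days, age_range,
                                 order = age_poly_order)
    for (j in seq_len(ncol(P))) cols[[paste0("age_", colnames(P)[j])]] <- P[, j]
  }
  if (variant == "RRM") cols[["ls_x"]] <- x
  if (variant == "LWA") cols[["ls_n"]] <- as.numeric(nvec)
  X <- do.call(cbind, cols)

  # drop aliased columns so X has full column rank
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    X <- X[, keep, drop = FALSE]
  }
  fixed_labels <- colnames(X)
  p <- ncol(X)

  y <- litters$litter_weight_g
  if (variant == "ABW") y <- y / nvec
  zval <- if (variant == "RRM") x else rep(1, nlit)
  Zd <- Matrix::sparseMatrix(i = seq_len(nlit), j = dam_idx, x = zval,
                             dims = c(nlit, m))
  Zlist <- list(dam = Zd)
  if (include_sire) {
    Zlist$sire <- Matrix::sparseMatrix(i = seq_len(nlit), j = sire_idx,
                                       x = zval, dims = c(nlit, m))
  }
  structure(list(
    y = y, X = Matrix::Matrix(X, sparse = TRUE), Zlist = Zlist,
    x = x, n = nvec, p = p, m = m, nlit = nlit,
    variant = variant, n_max = n_max, age_range = age_range,
    age_poly_order = age_poly_order,
    dam_idx = dam_idx, sire_idx = sire_idx,
    ped_ids = ped$id,
    fixed_labels = fixed_labels,
    generation = litters$generation,
    litter_id = litters$litter_id
  ), class = "rrm_design")
}
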