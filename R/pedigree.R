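#' Construct a validated pedigree
#'
#' Builds a topologically sorted pedigree object from parallel vectors of
#' animal, sire and dam identifiers. Unknown parents are coded as `NA` and
#' treated as unrelated base-population founders. The returned object stores
#' dense internal integer ids (parents always precede offspring) together
#' with a map back to the external identifiers.
#'
#' @param animal character or integer vector of unique animal identifiers.
#' @param sire,dam parent identifiers, `NA` (or a missing token already
#'   converted to `NA`) when unknown.
#' @param generation optional non-negative integer vector of discrete
#'   generation numbers; retained for reporting and used by the simulator.
#' @param add_missing_parents if `TRUE`, parents that never appear in
#'   `animal` are silently added as founders; if `FALSE` (default) they
#'   raise an error.
#' @return An object of class `rrm_pedigree`: a list with elements
#'   `id` (external ids in internal order), `sire`, `dam` (internal integer
#'   indices, 0 = unknown), `generation`, `depth` (longest ancestral path,
#'   founders 0) and `n`.
#' @examples
#' ped <- pedigree(c("s1", "d1", "x"), c(NA, NA, "s1"), c(NA, NA, "d1"))
#' inbreeding(ped)
#' @export
pedigree <- function(animal, sire, dam, generation = NULL,
                     add_missing_parents = FALSE) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyNA(animal)) stop("missing animal id")
  if (anyDuplicated(animal)) {
    stop("duplicate animal ids: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  n0 <- length(animal)
  if (length(sire) != n0 || length(dam) != n0)
    stop("animal, sire and dam must have equal length")
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("cyclic ancestry: animal listed as its own parent")

  parents <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  undeclared <- setdiff(parents, animal)
  gen <- if (is.null(generation)) rep(NA_integer_, n0) else as.integer(generation)
  if (length(undeclared)) {
    if (!add_missing_parents) {
      stop("parent id(s) not declared as animals: ",
           paste(utils::head(undeclared, 5), collapse = ", "),
           if (length(undeclared) > 5) ", ..." else "",
           " (set add_missing_parents = TRUE to add them as founders)")
    }
    animal <- c(undeclared, animal)
    sire <- c(rep(NA_character_, length(undeclared)), sire)
    dam <- c(rep(NA_character_, length(undeclared)), dam)
    gen <- c(rep(0L, length(undeclared)), gen)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  # Kahn topological sort; also yields ancestral depth
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  depth <- integer(n)
  order <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    order[k] <- v
    for (ch in children[[v]]) {
      depth[ch] <- max(depth[ch], depth[v] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n) stop("cyclic ancestry in pedigree")

  pos <- integer(n)
  pos[order] <- seq_len(n)
  so <- si[order]
  do_ <- di[order]
  sire_new <- integer(n)
  dam_new <- integer(n)
  sire_new[so > 0L] <- pos[so[so > 0L]]
  dam_new[do_ > 0L] <- pos[do_[do_ > 0L]]
  structure(list(
    id = animal[order],
    sire = sire_new,
    dam = dam_new,
    generation = gen[order],
    depth = depth[order],
    n = n
  ), class = "rrm_pedigree")
}

#' @export
print.rrm_pedigree <- function(x, ...) {
  nf <- sum(x$sire == 0L & x$dam == 0L)
  cat("Pedigree:", x$n, "animals (", nf, "founders ),",
      "max ancestral depth", max(x$depth), "\n")
  invisible(x)
}

#' @export
as.data.frame.rrm_pedigree <- function(x, ...) {
  data.frame(
    animal = x$id,
    sire = ifelse(x$sire > 0L, x$id[pmax(x$sire, 1L)], NA_character_),
    dam = ifelse(x$dam > 0L, x$id[pmax(x$dam, 1L)], NA_character_),
    generation = x$generation,
    stringsAsFactors = FALSE
  )
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns `animal,sire,dam` and optionally
#' `generation`. Unknown parents may be encoded by any of the tokens in
#' `missing_tokens`.
#'
#' @param path path to the CSV file.
#' @param missing_tokens character tokens interpreted as "parent unknown".
#' @param add_missing_parents passed to [pedigree()].
#' @return An `rrm_pedigree` object.
#' @export
read_pedigree <- function(path, missing_tokens = c("0", "", "NA"),
                          add_missing_parents = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree CSV must have columns: ", paste(need, collapse = ", "))
  tok2na <- function(v) { v[v %in% missing_tokens] <- NA_character_; v }
  gen <- if ("generation" %in% names(df)) as.integer(df$generation) else NULL
  pedigree(df$animal, tok2na(df$sire), tok2na(df$dam), generation = gen,
           add_missing_parents = add_missing_parents)
}

# TRUE when every non-founder has both parents known and exactly one layer up,
# so relationships can be propagated generation-matrix-wise.
.is_layered <- function(ped) {
  i <- which(ped$sire > 0L | ped$dam > 0L)
  if (!length(i)) return(TRUE)
  all(ped$sire[i] > 0L & ped$dam[i] > 0L) &&
    all(ped$depth[i] - ped$depth[pmax(ped$sire[i], 1L)] == 1L) &&
    all(ped$depth[i] - ped$depth[pmax(ped$dam[i], 1L)] == 1L)
}

# Layered fast path: carry the full relationship matrix of one layer to the
# next; exact for pedigrees where all parents sit in the previous layer.
.inbreeding_layered <- function(ped) {
  n <- ped$n
  Fv <- numeric(n)
  layers <- split(seq_len(n), ped$depth)
  prev_idx <- layers[[1L]]
  Aprev <- diag(length(prev_idx))
  if (length(layers) > 1L) {
    for (l in 2L:length(layers)) {
      idx <- layers[[l]]
      s <- match(ped$sire[idx], prev_idx)
      d <- match(ped$dam[idx], prev_idx)
      if (anyNA(s) || anyNA(d)) stop("internal: pedigree not layered")
      M <- 0.5 * (Aprev[s, , drop = FALSE] + Aprev[d, , drop = FALSE])
      Anew <- 0.5 * (M[, s, drop = FALSE] + M[, d, drop = FALSE])
      Fv[idx] <- 0.5 * Aprev[cbind(s, d)]
      diag(Anew) <- 1 + Fv[idx]
      Aprev <- Anew
      prev_idx <- idx
    }
  }
  Fv
}

# General Meuwissen & Luo style traversal, vectorized over depth layers.
.inbreeding_general <- function(ped) {
  n <- ped$n
  sire <- ped$sire; dam <- ped$dam; depth <- ped$depth
  Fv <- numeric(n)
  d <- numeric(n)
  L <- numeric(n)
  inb <- logical(n)
  buckets <- vector("list", max(depth) + 1L)
  for (i in seq_len(n)) {
    s <- sire[i]; dd <- dam[i]
    fs <- if (s > 0L) Fv[s] else -1
    fd <- if (dd > 0L) Fv[dd] else -1
    d[i] <- 0.5 - 0.25 * (fs + fd)
    if (s == 0L || dd == 0L) next  # F = 0 with an unknown base parent
    L[i] <- 1
    buckets[[depth[i] + 1L]] <- i
    inb[i] <- TRUE
    acc <- 0
    touched <- integer(0)
    for (lev in seq(depth[i], 0L)) {
      ids <- buckets[[lev + 1L]]
      if (!length(ids)) next
      buckets[[lev + 1L]] <- integer(0)
      inb[ids] <- FALSE
      touched <- c(touched, ids)
      acc <- acc + sum(L[ids]^2 * d[ids])
      par <- c(sire[ids], dam[ids])
      val <- rep(0.5 * L[ids], 2L)
      keep <- par > 0L
      if (any(keep)) {
        par <- par[keep]; val <- val[keep]
        ag <- rowsum(val, par)
        pid <- as.integer(rownames(ag))
        L[pid] <- L[pid] + ag[, 1L]
        add <- pid[!inb[pid]]
        if (length(add)) {
          inb[add] <- TRUE
          for (lv in unique(depth[add]))
            buckets[[lv + 1L]] <- c(buckets[[lv + 1L]], add[depth[add] == lv])
        }
      }
    }
    L[touched] <- 0
    Fv[i] <- acc - 1
  }
  Fv
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F computed by the Meuwissen-Luo
#' recursive algorithm (with a fast exact path for strictly
#' generation-layered pedigrees). Animals with at least one unknown parent
#' have F = 0 because unknown parents are base-population founders.
#'
#' @param ped an [pedigree()] object.
#' @return numeric vector of F coefficients in internal order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "rrm_pedigree"))
  if (.is_layered(ped)) .inbreeding_layered(ped) else .inbreeding_general(ped)
}

#' Dense numerator relationship matrix
#'
#' Tabular-method additive relationship matrix A. Intended for small
#' pedigrees; refuse above `cap` animals (use [a_inverse()] for large ones).
#'
#' @param ped an [pedigree()] object.
#' @param cap maximum pedigree size for the dense computation.
#' @return dense symmetric matrix with `diag(A) = 1 + F`.
#' @export
a_matrix <- function(ped, cap = 2000) {
  stopifnot(inherits(ped, "rrm_pedigree"))
  n <- ped$n
  if (n > cap)
    stop("pedigree has ", n, " > ", cap,
         " animals; use a_inverse() for large pedigrees")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A[i, i] <- if (s > 0L && d > 0L) 1 + 0.5 * A[s, d] else 1
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s > 0L) v <- v + 0.5 * A[s, prev]
      if (d > 0L) v <- v + 0.5 * A[d, prev]
      A[i, prev] <- v
      A[prev, i] <- v
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of A-inverse by the Henderson/Quaas rules, always
#' accounting for inbreeding: each animal contributes 1/d_i to its diagonal
#' (and the usual -1/2, 1/4 multiples to parent entries), where
#' d_i = 0.5 - 0.25 (F_sire + F_dam) is the Mendelian sampling variance
#' scale and the F of an unknown parent is -1.
#'
#' @param ped an [pedigree()] object.
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with attributes
#'   `logdet` (log-determinant of A, i.e. sum of log d_i) and `F`
#'   (inbreeding coefficients).
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "rrm_pedigree"))
  n <- ped$n
  Fv <- inbreeding(ped)
  s <- ped$sire; d <- ped$dam
  fs <- ifelse(s > 0L, Fv[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0L, Fv[pmax(d, 1L)], -1)
  dms <- 0.5 - 0.25 * (fs + fd)
  b <- 1 / dms
  ii <- seq_len(n)
  ti <- ii; tj <- ii; tx <- b
  hs <- s > 0L
  hd <- d > 0L
  add <- function(i, j, x) {
    ti <<- c(ti, i, j); tj <<- c(tj, j, i); tx <<- c(tx, x, x)
  }
  if (any(hs)) {
    add(ii[hs], s[hs], -b[hs] / 2)
    ti <- c(ti, s[hs]); tj <- c(tj, s[hs]); tx <- c(tx, b[hs] / 4)
  }
  if (any(hd)) {
    add(ii[hd], d[hd], -b[hd] / 2)
    ti <- c(ti, d[hd]); tj <- c(tj, d[hd]); tx <- c(tx, b[hd] / 4)
  }
  both <- hs & hd
  if (any(both)) add(s[both], d[both], b[both] / 4)
  ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                               symmetric = FALSE)
  ainv <- Matrix::forceSymmetric(Matrix::drop0((ainv + Matrix::t(ainv)) / 2))
  attr(ainv, "logdet") <- sum(log(dms))
  attr(ainv, "F") <- Fv
  ainv
}

#' Export a sparse matrix as coordinate triplets
#'
#' Writes `row,col,value` text (CSV) for debugging or interchange, keeping
#' only the stored (upper) triangle of a symmetric sparse matrix.
#'
#' @param m a sparse matrix (e.g. from [a_inverse()]).
#' @param path output file path.
#' @export
write_sparse_triplets <- function(m, path) {
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i <= tm@j
  df <- data.frame(row = tm@i[keep] + 1L, col = tm@j[keep] + 1L,
                   value = tm@x[keep])
  df <- df[order(df$col, df$row), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
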