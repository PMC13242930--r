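# Shared fixtures built in code: small pedigrees and litter tables.

# trio: two founders and their offspring
trio_ped <- function() {
  pedigree(c("s1", "d1", "o1"), c(NA, NA, "s1"), c(NA, NA, "d1"),
           generation = c(0L, 0L, 1L))
}

# full sibs and their inbred offspring
fullsib_ped <- function() {
  pedigree(c("s", "d", "a", "b", "x"),
           c(NA, NA, "s", "s", "a"),
           c(NA, NA, "d", "d", "b"))
}

# random general pedigree: parents drawn from earlier animals or unknown
random_pedigree <- function(n, p_unknown = 0.25, seed = 1) {
  set.seed(seed)
  ids <- sprintf("R%04d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (stats::runif(1) > p_unknown)
      sire[i] <- ids[sample.int(i - 1L, 1L)]
    if (stats::runif(1) > p_unknown) {
      d <- ids[sample.int(i - 1L, 1L)]
      if (!identical(d, sire[i])) dam[i] <- d
    }
  }
  pedigree(ids, sire, dam)
}

# litter records over random dam/sire pairs of a pedigree
random_litters <- function(ped, nlit, n_max = 16, seed = 1) {
  set.seed(seed)
  n <- ped$n
  dam <- sample(ped$id, nlit, replace = TRUE)
  sire <- sample(ped$id, nlit, replace = TRUE)
  ls <- sample.int(n_max, nlit, replace = TRUE)
  data.frame(litter_id = sprintf("L%04d", seq_len(nlit)),
             dam = dam, sire = sire,
             generation = sample(1:3, nlit, replace = TRUE),
             mating_age_days = round(stats::runif(nlit, 60, 150)),
             litter_size = ls,
             litter_weight_g = pmax(stats::rnorm(nlit, 1.8 * ls, 2), 0.5),
             stringsAsFactors = FALSE)
}

# small simulated dataset for fitting tests
small_sim <- function(seed = 1, ngen = 5, pairs = 25, ...) {
  cfg <- sim_config(n_generations = ngen, pairs_per_generation = pairs,
                    seed = seed, ...)
  list(cfg = cfg, sim = simulate_dataset(cfg))
}

fast_ctl <- function(...) rrm_control(se = FALSE, pev = FALSE, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
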