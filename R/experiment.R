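# Scaled-down experiment driver: generate model trees per regime, evolve
# 100-gene genomes, reconstruct, and report FP/FN (and wall time, for
# information only) per replicate with averages.

#' Run a simulation experiment for one regime
#'
#' Regimes: `"uniform"` (uniform-random topology, integer edge lengths
#' U\{0..16\}), `"bd"` (pure-birth topology, same length regime),
#' `"skew1"` / `"skew2"` (pure-birth topology, log2-skewed lengths scaled
#' to diameter `1*g` / `2*g`).
#'
#' @param regime one of `"uniform"`, `"bd"`, `"skew1"`, `"skew2"`.
#' @param n genomes per replicate.
#' @param replicates number of model trees.
#' @param seed base RNG seed; replicate `i` uses `seed + i`.
#' @param g genes per genome (default 100).
#' @param params [dcm_params()].
#' @return an `experiment_result`: data frame `table` with one row per
#'   replicate (`fp`, `fn`, `time_s`) and an `averages` row.
#' @export
run_experiment <- function(regime = c("uniform", "bd", "skew1", "skew2"),
                           n = 20L, replicates = 10L, seed = 1L,
                           g = 100L, params = dcm_params()) {
  regime <- match.arg(regime)
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    rs <- seed + i
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      mt <- simulate_regime(regime, n, g, rs)
      mt <- evolve_genomes(mt, g = g)
      st <- reconstruct(mt$genomes, params)
      acc <- fp_fn(st$tree, mt$tree)
      list(fp = acc$fp, fn = acc$fn, ok = TRUE)
    }, error = function(e) list(fp = NA_integer_, fn = NA_integer_,
                                ok = FALSE, msg = conditionMessage(e)))
    dt <- proc.time()[["elapsed"]] - t0
    rows[[i]] <- data.frame(replicate = i, seed = rs, fp = res$fp,
                            fn = res$fn, time_s = round(dt, 2),
                            finished = res$ok)
    if (!res$ok) message("replicate ", i, " failed: ", res$msg)
  }
  tab <- do.call(rbind, rows)
  fin <- tab[tab$finished, , drop = FALSE]
  avg <- data.frame(replicate = NA_integer_, seed = NA_integer_,
                    fp = mean(fin$fp), fn = mean(fin$fn),
                    time_s = mean(fin$time_s), finished = NA)
  structure(list(regime = regime, n = n, g = g, table = tab,
                 averages = avg),
            class = "experiment_result")
}

# one seeded model tree per regime (a single RNG stream per replicate:
# topology, lengths and inversion draws all follow from `seed`)
simulate_regime <- function(regime, n, g, seed) {
  set.seed(seed)
  switch(regime,
    uniform = uniform_random_tree(n, 0L, 16L),
    bd = uniform_lengths(birth_death_tree(n, birth = 0.001, death = 0),
                         0L, 16L),
    skew1 = skew_and_scale(birth_death_tree(n, birth = 0.001, death = 0),
                           diameter_factor = 1, g = g),
    skew2 = skew_and_scale(birth_death_tree(n, birth = 0.001, death = 0),
                           diameter_factor = 2, g = g))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("regime:", x$regime, " n =", x$n, " g =", x$g, "\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("averages: FP = %.2f  FN = %.2f  time = %.1fs\n",
              x$averages$fp, x$averages$fn, x$averages$time_s))
  invisible(x)
}
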