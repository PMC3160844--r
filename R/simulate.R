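# Simulators: model trees (uniform-random topology, pure-birth
# birth-death), edge-length regimes (discrete uniform, skewed log2
# multipliers scaled to a target diameter), and inversion evolution of
# signed gene orders along a model tree.

#' Uniform-random unrooted binary model tree
#'
#' Topology drawn uniformly over the `(2n-5)!!` unrooted binary
#' topologies by sequential leaf addition (each new leaf attaches to an
#' edge chosen uniformly); integer edge lengths sampled uniformly from
#' `length_low..length_high`.
#'
#' @param n number of leaves (>= 3).
#' @param length_low,length_high inclusive bounds of the discrete uniform
#'   edge-length distribution.
#' @param seed optional RNG seed.
#' @return a `model_tree`: `tree` (a `labeled_tree` with `lengths` the
#'   per-edge inversion counts), `leaves`, `seed`.
#' @export
uniform_random_tree <- function(n, length_low = 0L, length_high = 16L,
                                seed = NULL) {
  if (n < 3L) stop("uniform_random_tree requires n >= 3")
  if (!is.null(seed)) set.seed(seed)
  nms <- sprintf("L%02d", seq_len(n))
  # start from the 3-leaf star
  edges <- matrix(c(1L, 4L, 2L, 4L, 3L, 4L), ncol = 2, byrow = TRUE)
  nv <- 4L
  if (n > 3L) for (k in 4L:n) {
    e <- sample.int(nrow(edges), 1L)
    a <- edges[e, 1L]; b <- edges[e, 2L]
    w <- nv + 1L; leafv <- nv + 2L; nv <- nv + 2L
    edges[e, ] <- c(a, w)
    edges <- rbind(edges, c(w, b), c(leafv, w))
  }
  # vertex ids: leaves occupy 1..n? They don't after insertion; rebuild:
  # leaves are ids 1..3 and the even-step appended leaf ids; remap so
  # leaves come first
  leaf_ids <- c(1L, 2L, 3L, if (n > 3L) 4L + 2L * seq_len(n - 3L) else integer(0))
  int_ids <- setdiff(seq_len(nv), leaf_ids)
  newid <- integer(nv)
  newid[leaf_ids] <- seq_len(n)
  newid[int_ids] <- n + seq_along(int_ids)
  edges <- cbind(newid[edges[, 1L]], newid[edges[, 2L]])
  lens <- sample.int(length_high - length_low + 1L, nrow(edges),
                     replace = TRUE) + length_low - 1L
  tr <- lt_make(edges, vector("list", nv),
                c(nms, rep("", nv - n)),
                c(rep(TRUE, n), rep(FALSE, nv - n)),
                lengths = as.numeric(lens))
  structure(list(tree = tr, leaves = nms, seed = seed,
                 regime = "uniform"),
            class = "model_tree")
}

#' Pure-birth (Yule) birth-death model tree
#'
#' Runs a continuous-time pure-birth process (death rate 0) until `n`
#' tips exist. The returned edge lengths are the waiting-time durations;
#' length regimes for inversion counts are assigned afterwards (uniform
#' integers or [skew_and_scale()]).
#'
#' @param n number of tips (>= 3).
#' @param birth birth rate per lineage (default 0.001).
#' @param death death rate; only 0 is supported.
#' @param seed optional RNG seed.
#' @return a `model_tree` with time-duration edge lengths.
#' @export
birth_death_tree <- function(n, birth = 0.001, death = 0, seed = NULL) {
  if (n < 3L) stop("birth_death_tree requires n >= 3")
  if (death != 0) stop("only the pure-birth regime (death = 0) is supported")
  if (!is.null(seed)) set.seed(seed)
  # vertices: tips appear as they are born; internal vertices at splits.
  # lineage bookkeeping: active lineages each have a pending edge start.
  nms <- sprintf("L%02d", seq_len(n))
  # start with root (internal) and two lineages
  nv <- 1L
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  t_now <- 0
  active_parent <- c(1L, 1L)   # parent vertex of each active lineage
  active_birth <- c(0, 0)      # time at which the lineage started
  while (length(active_parent) < n) {
    k <- length(active_parent)
    t_now <- t_now + rexp(1L, rate = birth * k)
    i <- sample.int(k, 1L)
    # lineage i speciates: create an internal vertex, two new lineages
    nv <- nv + 1L
    edges <- rbind(edges, c(active_parent[i], nv))
    lens <- c(lens, t_now - active_birth[i])
    active_parent <- c(active_parent[-i], nv, nv)
    active_birth <- c(active_birth[-i], t_now, t_now)
  }
  # close tips at the final event time plus one more waiting time
  t_end <- t_now + rexp(1L, rate = birth * n)
  tipv <- integer(0)
  for (i in seq_along(active_parent)) {
    nv <- nv + 1L
    edges <- rbind(edges, c(active_parent[i], nv))
    lens <- c(lens, t_end - active_birth[i])
    tipv <- c(tipv, nv)
  }
  # remap: tips first
  int_ids <- setdiff(seq_len(nv), tipv)
  newid <- integer(nv)
  newid[tipv] <- seq_len(n)
  newid[int_ids] <- n + seq_along(int_ids)
  edges <- cbind(newid[edges[, 1L]], newid[edges[, 2L]])
  tr <- lt_make(edges, vector("list", nv),
                c(nms, rep("", nv - n)),
                c(rep(TRUE, n), rep(FALSE, nv - n)),
                lengths = lens)
  structure(list(tree = tr, leaves = nms, seed = seed, regime = "bd",
                 root = n + 1L),
            class = "model_tree")
}

#' Assign integer uniform edge lengths to a model tree
#'
#' @param mt a `model_tree`.
#' @param length_low,length_high inclusive integer bounds.
#' @return the model tree with integer edge lengths.
#' @export
uniform_lengths <- function(mt, length_low = 0L, length_high = 16L) {
  m <- nrow(mt$tree$edges)
  mt$tree$lengths <- as.numeric(sample.int(length_high - length_low + 1L,
                                           m, replace = TRUE) +
                                  length_low - 1L)
  mt
}

#' Skew edge lengths and scale the tree to a target diameter
#'
#' Each provisional edge length is multiplied by `2^s` with
#' `s ~ Uniform(-2, 2)` (a log2-uniform multiplier spanning 0.25 to 4,
#' producing a right-skewed length distribution), then all lengths are
#' scaled by one constant so the leaf-to-leaf diameter equals
#' `diameter_factor * g`, and rounded to nonnegative integers.
#'
#' @param mt a `model_tree` with positive provisional lengths.
#' @param diameter_factor 1 or 2.
#' @param g genes per genome (default 100).
#' @param seed optional RNG seed.
#' @return the model tree with integer edge lengths.
#' @export
skew_and_scale <- function(mt, diameter_factor = 1, g = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- mt$tree$lengths
  if (is.null(lens) || all(lens == 0)) stop("model tree has no edge lengths")
  s <- runif(length(lens), -2, 2)
  lens <- lens * 2^s
  dia <- tree_diameter(mt$tree, lens)
  if (dia <= 0) stop("zero-diameter tree cannot be scaled")
  lens <- lens * (diameter_factor * g / dia)
  mt$tree$lengths <- pmax(round(lens), 0)
  mt
}

# leaf-to-leaf diameter under the given edge lengths
tree_diameter <- function(tr, lens = tr$lengths) {
  adj <- lt_adj(tr)
  elen <- matrix(NA_real_, lt_nv(tr), lt_nv(tr))
  for (k in seq_len(nrow(tr$edges))) {
    a <- tr$edges[k, 1L]; b <- tr$edges[k, 2L]
    elen[a, b] <- lens[k]; elen[b, a] <- lens[k]
  }
  leaves <- which(tr$leaf)
  dmax <- 0
  for (s in leaves) {
    dist <- rep(NA_real_, lt_nv(tr))
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + elen[v, w]
        queue <- c(queue, w)
      }
    }
    dmax <- max(dmax, max(dist[leaves]))
  }
  dmax
}

#' Evolve genomes along a model tree by inversions
#'
#' The ancestor is the identity permutation of `g` genes; a pre-order
#' traversal applies exactly `edge length` inversions per edge. Each
#' inversion samples its length `L` uniformly from `1..g` (or from a
#' rounded, clamped gamma distribution) and its start uniformly from the
#' `g - L + 1` possible positions.
#'
#' @param mt a `model_tree` with integer edge lengths.
#' @param g genes per genome.
#' @param length_dist `"uniform"` or `"gamma"`.
#' @param gamma_shape,gamma_rate parameters when `length_dist = "gamma"`.
#' @param seed optional RNG seed.
#' @return the model tree with every vertex labeled (`$tree`), plus
#'   `$genomes`, the [genome_set()] of leaf genomes.
#' @export
evolve_genomes <- function(mt, g = 100L, length_dist = c("uniform", "gamma"),
                           gamma_shape = 1, gamma_rate = 0.1, seed = NULL) {
  length_dist <- match.arg(length_dist)
  if (!is.null(seed)) set.seed(seed)
  tr <- mt$tree
  counts <- as.integer(round(tr$lengths))
  if (any(counts < 0)) stop("negative edge count")
  adj <- lt_adj(tr)
  root <- if (!is.null(mt$root)) mt$root else which(!tr$leaf)[1L]
  if (is.na(root)) root <- 1L
  labels <- vector("list", lt_nv(tr))
  labels[[root]] <- seq_len(g)
  draw_inversion <- function(genome) {
    L <- if (length_dist == "uniform") sample.int(g, 1L)
    else max(1L, min(g, as.integer(round(stats::rgamma(1L, shape = gamma_shape,
                                                       rate = gamma_rate)))))
    start <- if (g - L + 1L == 1L) 1L else sample.int(g - L + 1L, 1L)
    apply_inversion(genome, start, start + L - 1L)
  }
  edge_id <- function(a, b) {
    which((tr$edges[, 1L] == a & tr$edges[, 2L] == b) |
          (tr$edges[, 2L] == a & tr$edges[, 1L] == b))[1L]
  }
  stack <- list(c(root, NA_integer_))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top[1L]; from <- top[2L]
    for (w in adj[[v]]) {
      if (!is.na(from) && w == from) next
      genome <- labels[[v]]
      k <- edge_id(v, w)
      nk <- counts[k]
      if (nk > 0L) for (t in seq_len(nk)) genome <- draw_inversion(genome)
      labels[[w]] <- as.integer(unclass(genome))
      stack[[length(stack) + 1L]] <- c(w, v)
    }
  }
  tr$labels <- labels
  mt$tree <- tr
  leaves <- which(tr$leaf)
  mt$genomes <- genome_set(lapply(leaves, function(v) {
    gene_order(labels[[v]], tr$vnames[v])
  }))
  mt
}

#' @export
print.model_tree <- function(x, ...) {
  cat("model_tree (", x$regime, "): ", length(x$leaves), " leaves\n",
      sep = "")
  cat(write_newick(x$tree), "\n")
  invisible(x)
}
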