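# Independent oracles and fixture builders used across the test suite.
# The oracles deliberately avoid the package's C++ machinery: distances
# come from breadth-first search over the inversion move graph, medians
# from exhaustive search over that graph, and exhaustive tree scores from
# explicit topology enumeration.

rev_apply_oracle <- function(p, i, j) {
  p[i:j] <- -rev(p[i:j])
  p
}

all_moves <- function(g) {
  out <- list()
  for (i in 1:g) for (j in i:g) out[[length(out) + 1L]] <- c(i, j)
  out
}

# BFS shortest path in the inversion move graph from a to b (early exit)
bfs_inversion_distance <- function(a, b, max_depth = 10L) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  if (identical(a, b)) return(0L)
  g <- length(a)
  moves <- all_moves(g)
  key <- function(p) paste(p, collapse = ",")
  target <- key(b)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(key(a), TRUE, seen)
  frontier <- list(a)
  for (d in seq_len(max_depth)) {
    nxt <- list()
    for (p in frontier) {
      for (m in moves) {
        q <- rev_apply_oracle(p, m[1L], m[2L])
        k <- key(q)
        if (k == target) return(d)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  stop("oracle BFS exceeded max depth")
}

# exhaustive median oracle: breadth-first enumeration over the move
# graph from the cheapest corner, bounded by f(m) >= d(s, m) + d(other
# pair). Distances inside the enumeration use inversion_distance, which
# the distance tests validate against the BFS oracle independently; the
# exhaustiveness of the candidate enumeration is what this oracle
# contributes.
oracle_median_score <- function(a, b, c) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  c <- as.integer(unclass(c))
  g <- length(a)
  moves <- all_moves(g)
  dd <- function(x, y) cpp_dist_oracle(x, y)
  f <- function(x) dd(x, a) + dd(x, b) + dd(x, c)
  corners <- list(a, b, c)
  fs <- vapply(corners, f, integer(1))
  s <- corners[[which.min(fs)]]
  best <- min(fs)
  dpair <- c(dd(b, c), dd(a, c), dd(a, b))[which.min(fs)]
  key <- function(p) paste(p, collapse = ",")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(key(s), TRUE, seen)
  frontier <- list(s)
  lev <- 0L
  while (length(frontier) && lev + 1L + dpair < best) {
    lev <- lev + 1L
    nxt <- list()
    for (p in frontier) for (m in moves) {
      q <- rev_apply_oracle(p, m[1L], m[2L])
      k <- key(q)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        fq <- f(q)
        if (fq < best) best <- fq
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    frontier <- nxt
  }
  best
}

# a uniformly chosen inversion window, robust to the scalar-sample gotcha
rand_ij <- function(g) {
  i <- sample.int(g, 1L)
  j <- i + sample.int(g - i + 1L, 1L) - 1L
  c(i, j)
}

cpp_dist_oracle <- function(x, y) {
  inversion_distance(gene_order(x, "x"), gene_order(y, "y"))
}

random_genome <- function(g, k, name = "G") {
  p <- seq_len(g)
  if (k > 0L) for (t in seq_len(k)) {
    ij <- rand_ij(g)
    p <- rev_apply_oracle(p, ij[1L], ij[2L])
  }
  gene_order(p, name)
}

# all unrooted binary topologies over the given leaf names (leaves get
# ids 1..n, internal vertices n+1..2n-2), as labeled_tree objects with
# unlabeled internal vertices
enumerate_topologies <- function(nms) {
  n <- length(nms)
  stopifnot(n >= 3L)
  base <- list(matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L),
                      ncol = 2, byrow = TRUE))
  if (n > 3L) for (k in 4:n) {
    w <- n + (k - 2L)
    nxt <- list()
    for (m in base) {
      for (e in seq_len(nrow(m))) {
        m2 <- m
        a <- m2[e, 1L]; b <- m2[e, 2L]
        m2[e, ] <- c(a, w)
        m2 <- rbind(m2, c(w, b), c(k, w))
        nxt[[length(nxt) + 1L]] <- m2
      }
    }
    base <- nxt
  }
  lapply(base, function(m) {
    spectree:::lt_make(m, vector("list", 2L * n - 2L),
                       c(nms, rep("", n - 2L)),
                       c(rep(TRUE, n), rep(FALSE, n - 2L)))
  })
}

# exhaustive maximum-parsimony score over all topologies for a genome set
exhaustive_mp_score <- function(set, params = dcm_params()) {
  nms <- names(set$genomes)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  best <- Inf
  for (tp in enumerate_topologies(nms)) {
    for (i in seq_along(nms)) tp$labels[[i]] <- set$genomes[[i]]
    tp <- spectree:::lt_fill_labels(tp, cache, params$median_budget)
    st <- score_topology(tp, params$max_passes, params$median_budget, cache)
    if (st$score < best) best <- st$score
  }
  best
}

# hand-built model tree from a Newick skeleton with given integer edge
# lengths, evolved into genomes
build_model <- function(newick, lengths = NULL, g = 50L, seed = 1L) {
  tr <- read_newick(text = newick)
  if (!is.null(lengths)) tr$lengths <- as.numeric(lengths)
  mt <- structure(list(tree = tr, leaves = sort(tr$vnames[tr$leaf]),
                       seed = seed, regime = "manual"),
                  class = "model_tree")
  evolve_genomes(mt, g = g, seed = seed)
}

# the incompatible-but-recoverable configuration: three clades A, B, C;
# the overlap holds the genomes nearest the clade junctions, and the
# exclusive regions straddle clades without a separating edge
three_clade_fixture <- function(seed = 9) {
  nwk <- paste0("((A0:3,(A1:3,(A2:3,A3:3):3):3):4,",
                "(B0:3,(B1:3,(B2:3,(B3:3,B4:3):3):3):3):4,",
                "(C0:3,(C1:3,(C2:3,(C3:3,C4:3):3):3):3):4);")
  build_model(nwk, g = 60, seed = seed)
}

canonical_topology <- function(tr) {
  paste(sort(unique(spectree:::lt_internal_splits(tr))), collapse = " ; ")
}
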