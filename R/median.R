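# Inversion medians and GRAPPA-style iterative scoring of a fixed
# topology: each internal vertex is repeatedly relabeled with the median
# of its three neighbors until the parsimony score converges.

#' Inversion median of three genomes
#'
#' Finds a genome minimizing the summed inversion distance to the three
#' inputs. The search is an exact breadth-first branch-and-bound over
#' inversion sequences from the input with the smallest distance sum,
#' pruned with the metric bound `f(m) >= d(s, m) + d(pair)` and the
#' half-perimeter lower bound. When the node budget is exceeded the
#' best-so-far genome is refined by a greedy descent over candidate
#' reversals and flagged `heuristic`.
#'
#' @param a,b,c gene orders over the same gene set.
#' @param budget node budget for the exact search.
#' @return a `median_solution`: `median` (gene order), `score`,
#'   `heuristic`, `lower_bound`.
#' @examples
#' m <- inversion_median(gene_order(1:4), gene_order(c(2, 1, 3, 4)),
#'                       gene_order(c(1, 2, -4, -3)))
#' m$score
#' @export
inversion_median <- function(a, b, c, budget = 20000L) {
  p1 <- check_pair(a, b); p2 <- check_pair(a, c)
  r <- cpp_inversion_median(p1$a, p1$b, p2$b, as.integer(budget))
  structure(list(median = gene_order(r$median, "median"),
                 score = r$score, heuristic = r$heuristic,
                 lower_bound = r$lower_bound),
            class = "median_solution")
}

#' @export
print.median_solution <- function(x, ...) {
  cat("inversion median: score", x$score,
      if (x$heuristic) "(heuristic)" else "(exact)", "\n")
  invisible(x)
}

# memoized median over integer vectors; cache is an environment
median3 <- function(cache, a, b, c, budget) {
  ord <- order(vapply(list(a, b, c), function(x) paste(x, collapse = ","),
                      character(1)))
  tri <- list(a, b, c)[ord]
  key <- paste(vapply(tri, paste, character(1), collapse = ","),
               collapse = ";")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- cpp_inversion_median(tri[[1L]], tri[[2L]], tri[[3L]],
                            as.integer(budget))
  out <- list(median = r$median, score = r$score, heuristic = r$heuristic)
  cache[[key]] <- out
  out
}

#' Initialize the label of a newly created internal vertex
#'
#' The label is the inversion median of the genome being attached and the
#' two already-labeled neighboring genomes, mirroring the merge-order
#' labeling scheme in which every new ancestor is initialized from close,
#' already-reconstructed genomes.
#'
#' @param attached the genome joined at the new vertex.
#' @param n1,n2 the two neighbor labels (must be assigned).
#' @param budget median search budget.
#' @return a gene order.
#' @export
initialize_label <- function(attached, n1, n2, budget = 20000L) {
  if (is.null(n1) || is.null(n2)) {
    stop("initialize_label: neighbor label not yet assigned ",
         "(merge-order sequencing error)")
  }
  inversion_median(attached, n1, n2, budget)$median
}

#' Score a fixed topology by iterated median refinement
#'
#' Round-robin over the internal vertices (breadth-first order from the
#' first leaf): each internal label is replaced by the inversion median of
#' its three neighbors whenever that strictly lowers the tree score;
#' passes repeat until a full pass makes no change or `max_passes` is
#' reached. The score never increases across passes.
#'
#' @param tree a binary `labeled_tree` with all leaves labeled and initial
#'   internal labels present.
#' @param max_passes maximum refinement passes.
#' @param budget median search budget.
#' @param cache optional median cache environment.
#' @param alt_init additionally refine from a nearest-leaf initialization
#'   (each internal vertex starts at the median of its three closest
#'   leaves) and keep the better-scoring labeling.
#' @return a `scored_topology`: `tree` (relabeled), `score`, `iterations`.
#' @export
score_topology <- function(tree, max_passes = 50L, budget = 20000L,
                           cache = NULL, alt_init = TRUE) {
  if (is.null(cache)) cache <- new.env(hash = TRUE, parent = emptyenv())
  if (alt_init) {
    r1 <- score_topology(tree, max_passes, budget, cache, alt_init = FALSE)
    t2 <- nearest_leaf_init(tree, cache, budget)
    if (is.null(t2)) return(r1)
    r2 <- score_topology(t2, max_passes, budget, cache, alt_init = FALSE)
    return(if (r2$score < r1$score) r2 else r1)
  }
  nv <- lt_nv(tree)
  deg <- lt_degree(tree)
  internal <- which(!tree$leaf)
  if (length(internal) > 0L && any(deg[internal] != 3L)) {
    stop("score_topology requires a binary tree (internal degree 3)")
  }
  if (any(vapply(tree$labels, is.null, logical(1)))) {
    stop("score_topology requires initial labels on every vertex")
  }
  if (length(internal) == 0L) {
    return(structure(list(tree = lt_set_lengths_from_labels(tree),
                          score = tree_score(tree), iterations = 0L),
                     class = "scored_topology"))
  }
  adj <- lt_adj(tree)
  # fixed visit order: BFS from the lowest-id leaf
  start <- which(tree$leaf)[1L]
  if (is.na(start)) start <- 1L
  order_v <- integer(0)
  seen <- logical(nv); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (!tree$leaf[v]) order_v <- c(order_v, v)
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  d_of <- function(x, y) cpp_inv_dist(x, y)
  passes <- 0L
  repeat {
    changed <- FALSE
    passes <- passes + 1L
    for (v in order_v) {
      nbs <- adj[[v]]
      cur <- tree$labels[[v]]
      local_now <- sum(vapply(nbs, function(w) d_of(cur, tree$labels[[w]]),
                              integer(1)))
      m <- median3(cache, tree$labels[[nbs[1L]]], tree$labels[[nbs[2L]]],
                   tree$labels[[nbs[3L]]], budget)
      if (m$score < local_now) {
        tree$labels[[v]] <- m$median
        changed <- TRUE
      }
    }
    if (!changed || passes >= max_passes) break
  }
  # zero-collapse sweeps: a short internal edge whose split has no real
  # support should end up with identical endpoint labels rather than
  # asserting a phantom split. Two moves, both accepted only when the
  # score does not increase: (a) adopt an adjacent internal label; (b)
  # fuse an edge onto a common Steiner label computed from the four
  # outer neighbors.
  repeat {
    collapsed <- FALSE
    for (v in order_v) {
      nbs <- adj[[v]]
      cur <- tree$labels[[v]]
      local_now <- sum(vapply(nbs, function(w) d_of(cur, tree$labels[[w]]),
                              integer(1)))
      for (w in nbs) {
        if (tree$leaf[w]) next
        cand <- tree$labels[[w]]
        if (identical(cand, cur)) next
        local_new <- sum(vapply(nbs, function(z) d_of(cand, tree$labels[[z]]),
                                integer(1)))
        if (local_new <= local_now) {
          tree$labels[[v]] <- cand
          collapsed <- TRUE
          break
        }
      }
    }
    # joint endpoint relabeling of short internal-internal edges: search
    # a small pool of Steiner candidates for the pair (z_u, z_v); adopt a
    # strictly better pair, or an equal-cost pair that zeroes the edge
    for (k in seq_len(nrow(tree$edges))) {
      u <- tree$edges[k, 1L]; v <- tree$edges[k, 2L]
      if (tree$leaf[u] || tree$leaf[v]) next
      lu <- tree$labels[[u]]; lv <- tree$labels[[v]]
      duv <- d_of(lu, lv)
      if (duv == 0L || duv > 3L) next
      ou <- setdiff(adj[[u]], v); ov <- setdiff(adj[[v]], u)
      if (length(ou) != 2L || length(ov) != 2L) next
      outer <- c(tree$labels[ou], tree$labels[ov])
      cost_now <- duv +
        d_of(lu, outer[[1L]]) + d_of(lu, outer[[2L]]) +
        d_of(lv, outer[[3L]]) + d_of(lv, outer[[4L]])
      pool <- list(lu, lv)
      for (tri in list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                       c(3L, 4L, 1L), c(3L, 4L, 2L))) {
        pool[[length(pool) + 1L]] <-
          median3(cache, outer[[tri[1L]]], outer[[tri[2L]]],
                  outer[[tri[3L]]], budget)$median
      }
      best_pair <- NULL; best_cost <- cost_now; best_zero <- (duv == 0L)
      for (z1 in pool) {
        c1 <- d_of(z1, outer[[1L]]) + d_of(z1, outer[[2L]])
        for (z2 in pool) {
          cst <- c1 + d_of(z1, z2) +
            d_of(z2, outer[[3L]]) + d_of(z2, outer[[4L]])
          zero <- d_of(z1, z2) == 0L
          if (cst < best_cost || (cst == best_cost && zero && !best_zero)) {
            best_pair <- list(z1, z2); best_cost <- cst; best_zero <- zero
          }
        }
      }
      if (!is.null(best_pair)) {
        tree$labels[[u]] <- best_pair[[1L]]
        tree$labels[[v]] <- best_pair[[2L]]
        collapsed <- TRUE
      }
    }
    passes <- passes + 1L
    if (!collapsed || passes >= max_passes) break
  }
  tree <- lt_set_lengths_from_labels(tree)
  structure(list(tree = tree, score = tree_score(tree),
                 iterations = passes),
            class = "scored_topology")
}

# alternative initialization: each internal vertex starts from the
# inversion median of its three nearest leaves (hop distance, ties by
# vertex id); returns NULL for trees without internal vertices
nearest_leaf_init <- function(tree, cache, budget) {
  internal <- which(!tree$leaf)
  if (length(internal) == 0L) return(NULL)
  adj <- lt_adj(tree)
  nv <- lt_nv(tree)
  for (v in internal) {
    # BFS until three leaves found
    dist <- rep(NA_integer_, nv); dist[v] <- 0L
    queue <- v
    found <- integer(0)
    while (length(queue) && length(found) < 3L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[u]]) if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        if (tree$leaf[w]) found <- c(found, w) else queue <- c(queue, w)
      }
    }
    if (length(found) < 3L) return(NULL)
    found <- found[seq_len(3L)]
    tree$labels[[v]] <- median3(cache, tree$labels[[found[1L]]],
                                tree$labels[[found[2L]]],
                                tree$labels[[found[3L]]], budget)$median
  }
  tree
}

#' @export
print.scored_topology <- function(x, ...) {
  cat("scored_topology: parsimony score", x$score, "after", x$iterations,
      "refinement passes\n")
  cat(write_newick(x$tree), "\n")
  invisible(x)
}
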