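# Full pipeline: pairwise distances -> recursive spectral decomposition
# -> leaf-disk reconstruction (inversion medians) -> post-order merging.

#' Reconstruct a phylogeny for a genome set
#'
#' Computes the pairwise inversion distance matrix, builds the binary
#' disk tree by recursive spectral decomposition, reconstructs each leaf
#' disk of at most three genomes directly (the inversion median resolves
#' the single internal vertex), and recursively merges sibling disk
#' topologies (overlapping or non-overlapping per node). Identical
#' genomes are deduplicated before decomposition and re-attached as
#' zero-length cherries.
#'
#' @param set a [genome_set()].
#' @param params [dcm_params()].
#' @return a `scored_topology` over all input genomes; the score is
#'   recomputed from scratch on the final labeling.
#' @export
reconstruct <- function(set, params = dcm_params()) {
  stopifnot(inherits(set, "genome_set"))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  nms <- names(set$genomes)
  n <- length(nms)

  # deduplicate identical genomes (keep the first of each class)
  keys <- vapply(set$genomes, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  uniq_names <- nms[first]
  dup_of <- vapply(keys, function(k) uniq_names[match(k, keys[first])],
                   character(1))
  names(dup_of) <- nms
  uset <- structure(list(genomes = set$genomes[first], g = set$g),
                    class = "genome_set")

  tr <- reconstruct_unique(uset, params, cache)
  # re-attach duplicates as zero-length cherries on their representative
  for (nm in nms[!first]) {
    rep_nm <- dup_of[[nm]]
    u <- which(tr$leaf & tr$vnames == rep_nm)
    gen <- set$genomes[[nm]]
    if (nrow(tr$edges) == 0L) {
      # single-vertex tree
      w <- lt_nv(tr) + 1L
      tr$labels[[w]] <- gen
      tr$vnames <- c(tr$vnames, nm)
      tr$leaf <- c(tr$leaf, TRUE)
      tr <- lt_add_edge(tr, u, w)
      next
    }
    e <- which(tr$edges[, 1L] == u | tr$edges[, 2L] == u)[1L]
    sd <- lt_subdivide(tr, e)
    tr <- sd$tree
    tr$labels[[sd$v]] <- tr$labels[[u]]
    w <- lt_nv(tr) + 1L
    tr$labels[[w]] <- gen
    tr$vnames <- c(tr$vnames, nm)
    tr$leaf <- c(tr$leaf, TRUE)
    tr <- lt_add_edge(tr, sd$v, w)
  }
  tr <- lt_set_lengths_from_labels(tr)
  structure(list(tree = tr, score = tree_score(tr), iterations = NA_integer_),
            class = "scored_topology")
}

reconstruct_unique <- function(set, params, cache) {
  nms <- names(set$genomes)
  n <- length(nms)
  if (n <= 3L) return(small_disk_tree(set$genomes, params, cache))
  D <- pairwise_matrix(set, "inversion")
  dtree <- build_disk_tree(D, params)
  # each node resolves to the list of equal-parsimony trees (capped);
  # local ties are settled higher up where more genomes weigh in
  solve_node <- function(node) {
    if (is.null(node$children)) {
      return(list(small_disk_tree(set$genomes[node$disk], params, cache)))
    }
    l0 <- solve_node(node$children[[1L]])
    l1 <- solve_node(node$children[[2L]])
    ov <- nms[node$decomp$overlap]
    pool <- list(); pool_score <- Inf
    for (t0 in l0) for (t1 in l1) {
      st <- if (length(ov) == 0L) {
        merge_nonoverlapping(t0, t1, params, cache)
      } else {
        merge_overlapping(t0, t1, ov, params, cache)
      }
      for (cand in c(list(st), attr(st, "ties"))) {
        if (cand$score < pool_score) {
          pool <- list(cand$tree); pool_score <- cand$score
        } else if (cand$score == pool_score) {
          pool[[length(pool) + 1L]] <- cand$tree
        }
      }
    }
    # deduplicate by topology, order by least asserted resolution
    keys <- vapply(pool, function(tr) {
      paste(sort(unique(lt_internal_splits(tr))), collapse = ";")
    }, character(1))
    pool <- pool[!duplicated(keys)]
    ns <- vapply(pool, n_supported_edges, integer(1))
    pool <- pool[order(ns)]
    head(pool, params$max_ties)
  }
  out <- solve_node(dtree)
  out[[1L]]
}

# direct reconstruction for 1..3 genomes: vertex, edge, or star with a
# median-labeled center
small_disk_tree <- function(genomes, params, cache) {
  nms <- names(genomes)
  k <- length(genomes)
  if (k == 1L) return(lt_single(genomes[[1L]], nms[1L]))
  if (k == 2L) {
    return(lt_make(matrix(c(1L, 2L), ncol = 2), genomes, nms, c(TRUE, TRUE)))
  }
  m <- median3(cache, genomes[[1L]], genomes[[2L]], genomes[[3L]],
               params$median_budget)
  lt_make(matrix(c(1L, 4L, 2L, 4L, 3L, 4L), ncol = 2, byrow = TRUE),
          c(genomes, list(m$median)), c(nms, ""),
          c(TRUE, TRUE, TRUE, FALSE))
}
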