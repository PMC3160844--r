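# Merging disk sub-topologies into the parent disk's tree.
#
# Non-overlapping disks: find the closest cross pair of genomes (internal
# and leaf labels both count), bridge every pair of their incident edges
# (at most 3 x 3 = 9 candidates unless the minimum distance is tied), and
# keep the lowest-parsimony candidate.
#
# Overlapping disks: compare the two sub-topologies restricted to the
# overlap; collapse conflicting edges; glue the trees through a backbone
# built from the union of the (now compatible) overlap splits; expand
# every collapsed region by enumerating all binary resolutions; keep the
# lowest-parsimony candidate.

as_lt <- function(x) {
  if (inherits(x, "scored_topology")) x$tree else x
}

#' Merge the trees of two non-overlapping disks
#'
#' @param t0,t1 fully labeled trees (`labeled_tree` or `scored_topology`)
#'   with disjoint leaf sets.
#' @param params [dcm_params()].
#' @param cache optional median cache environment.
#' @return a `scored_topology` for the union of the leaves, with
#'   attributes `candidates` (number enumerated), `ties` (equal-score
#'   optima) and `closest_pairs`.
#' @export
merge_nonoverlapping <- function(t0, t1, params = dcm_params(),
                                 cache = NULL) {
  if (is.null(cache)) cache <- new.env(hash = TRUE, parent = emptyenv())
  tt0 <- as_lt(t0); tt1 <- as_lt(t1)
  if (lt_nv(tt0) == 0L || lt_nv(tt1) == 0L) stop("cannot merge empty trees")
  if (length(intersect(leaf_names(tt0), leaf_names(tt1)))) {
    stop("leaf sets overlap; use merge_overlapping")
  }
  # closest cross pair over all (internal and leaf) genome labels
  n0 <- lt_nv(tt0); n1 <- lt_nv(tt1)
  cross <- matrix(0L, n0, n1)
  for (i in seq_len(n0)) for (j in seq_len(n1)) {
    cross[i, j] <- cpp_inv_dist(tt0$labels[[i]], tt1$labels[[j]])
  }
  dmin <- min(cross)
  pairs <- which(cross == dmin, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]

  best <- NULL; best_score <- Inf
  ties <- list(); n_cand <- 0L; provenance <- character(0)
  for (pi in seq_len(nrow(pairs))) {
    u <- pairs[pi, 1L]; v <- pairs[pi, 2L]
    e0s <- which(tt0$edges[, 1L] == u | tt0$edges[, 2L] == u)
    e1s <- which(tt1$edges[, 1L] == v | tt1$edges[, 2L] == v)
    if (length(e0s) == 0L) e0s <- 0L   # single-vertex tree: attach directly
    if (length(e1s) == 0L) e1s <- 0L
    for (e0 in e0s) for (e1 in e1s) {
      un <- lt_union(tt0, tt1)
      tr <- un$tree; voff <- un$offset; eoff <- nrow(tt0$edges)
      if (e0 > 0L) {
        sd <- lt_subdivide(tr, e0)
        tr <- sd$tree; x0 <- sd$v
        ends0 <- c(tt0$edges[e0, 1L], tt0$edges[e0, 2L])
        lab_x0 <- median3(cache, tt1$labels[[v]], tt0$labels[[ends0[1L]]],
                          tt0$labels[[ends0[2L]]],
                          params$median_budget)$median
        tr$labels[[x0]] <- lab_x0
      } else {
        x0 <- u; lab_x0 <- tt0$labels[[u]]
      }
      if (e1 > 0L) {
        sd <- lt_subdivide(tr, e1 + eoff)
        tr <- sd$tree; x1 <- sd$v
        ends1 <- c(tt1$edges[e1, 1L], tt1$edges[e1, 2L]) + voff
        tr$labels[[x1]] <- median3(cache, lab_x0, tr$labels[[ends1[1L]]],
                                   tr$labels[[ends1[2L]]],
                                   params$median_budget)$median
      } else {
        x1 <- v + voff
      }
      tr <- lt_add_edge(tr, x0, x1)
      st <- score_topology(tr, params$max_passes, params$median_budget,
                           cache)
      n_cand <- n_cand + 1L
      provenance <- c(provenance, paste0("pair(", u, ",", v, ") edges(",
                                         e0, ",", e1, ")"))
      if (st$score < best_score) {
        best <- st; best_score <- st$score; ties <- list(st)
      } else if (st$score == best_score) {
        ties[[length(ties) + 1L]] <- st
        # equal parsimony: prefer the candidate asserting fewer positive-
        # length internal edges (the least-resolved equally good tree)
        if (n_supported_edges(st$tree) < n_supported_edges(best$tree)) {
          best <- st
        }
      }
    }
  }
  attr(best, "candidates") <- n_cand
  attr(best, "ties") <- ties
  attr(best, "closest_pairs") <- pairs
  attr(best, "provenance") <- provenance
  best
}

# canonical split string for a set of leaf names over universe X
canon_split <- function(side, X) {
  ref <- sort(X)[1L]
  if (ref %in% side) side <- setdiff(X, side)
  paste(sort(side), collapse = "|")
}

# sides (as name vectors) of every edge of a tree over its leaf universe
edge_sides <- function(tr) {
  al <- leaf_names(tr)
  lapply(seq_len(nrow(tr$edges)), function(k) {
    side <- lt_side_of(tr, k, tr$edges[k, 1L])
    tr$vnames[intersect(side, which(tr$leaf))]
  })
}

splits_incompatible <- function(A, B, X) {
  Ac <- setdiff(X, A); Bc <- setdiff(X, B)
  length(intersect(A, B)) > 0L && length(intersect(A, Bc)) > 0L &&
    length(intersect(Ac, B)) > 0L && length(intersect(Ac, Bc)) > 0L
}

#' Find edges whose overlap-restricted splits conflict between two disks
#'
#' Restricts both trees to the overlap leaves (suppressing degree-2
#' vertices); an internal edge of one restricted tree conflicts when its
#' bipartition of the overlap is incompatible with some bipartition of
#' the other restricted tree. Returns, per tree, the original edge ids
#' whose restricted images conflict.
#'
#' @param t0,t1 trees containing all overlap genomes as leaves.
#' @param overlap character vector of overlap genome names (length >= 1).
#' @return list with `edges0`, `edges1` (integer edge ids).
#' @export
conflicting_overlap_edges <- function(t0, t1, overlap) {
  if (length(overlap) == 0L) {
    stop("empty overlap: use the non-overlapping merge")
  }
  tt0 <- as_lt(t0); tt1 <- as_lt(t1)
  X <- sort(overlap)
  r0 <- lt_restrict(tt0, X); r1 <- lt_restrict(tt1, X)
  info <- function(r) {
    if (nrow(r$edges) == 0L) {
      return(list(sides = list(), internal = integer(0)))
    }
    internal <- which(!r$leaf[r$edges[, 1L]] & !r$leaf[r$edges[, 2L]])
    sides <- lapply(internal, function(k) {
      side <- lt_side_of(r, k, r$edges[k, 1L])
      r$vnames[intersect(side, which(r$leaf))]
    })
    list(sides = sides, internal = internal)
  }
  i0 <- info(r0); i1 <- info(r1)
  conf0 <- logical(length(i0$internal)); conf1 <- logical(length(i1$internal))
  for (a in seq_along(i0$sides)) for (b in seq_along(i1$sides)) {
    if (splits_incompatible(i0$sides[[a]], i1$sides[[b]], X)) {
      conf0[a] <- TRUE; conf1[b] <- TRUE
    }
  }
  es0 <- attr(r0, "edge_src"); es1 <- attr(r1, "edge_src")
  list(edges0 = sort(unique(unlist(es0[i0$internal[conf0]]))),
       edges1 = sort(unique(unlist(es1[i1$internal[conf1]]))))
}

# Steiner structure of tr with respect to keep_names: which vertices lie
# on the subtree spanning the kept leaves, and the hanging pieces
lt_steiner_info <- function(tr, keep_names) {
  nv <- lt_nv(tr)
  adj <- lt_adj(tr)
  is_keep <- tr$leaf & tr$vnames %in% keep_names
  alive <- rep(TRUE, nv)
  deg <- lt_degree(tr)
  repeat {
    drop <- which(alive & !is_keep & deg <= 1L)
    if (length(drop) == 0L) break
    for (v in drop) {
      alive[v] <- FALSE
      for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
      deg[v] <- 0L
    }
  }
  # pieces: components of the removed vertices, each with its attachment
  seen <- alive
  pieces <- list()
  for (v0 in which(!alive)) {
    if (seen[v0]) next
    comp <- integer(0); stack <- v0; seen[v0] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!alive[w] && !seen[w]) {
        seen[w] <- TRUE; stack <- c(stack, w)
      }
    }
    va <- NA_integer_; pb <- NA_integer_
    for (v in comp) for (w in adj[[v]]) if (alive[w]) {
      va <- w; pb <- v
    }
    pieces[[length(pieces) + 1L]] <- list(vertices = sort(comp), va = va,
                                          pb = pb)
  }
  sdeg <- integer(nv)
  for (v in which(alive)) sdeg[v] <- sum(alive[adj[[v]]])
  list(alive = alive, sdeg = sdeg, pieces = pieces)
}

# partition signature of a vertex: the multiset of leaf-name components
# obtained by removing the vertex (identifies vertices across trees with
# identical split sets)
vertex_signature <- function(tr, v) {
  adj <- lt_adj(tr)
  leaves_of <- function(w) {
    # component containing w after removing v
    seen <- logical(lt_nv(tr)); seen[v] <- TRUE; seen[w] <- TRUE
    stack <- w
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; stack <- c(stack, y) }
    }
    seen[v] <- FALSE
    sort(tr$vnames[which(seen & tr$leaf)])
  }
  parts <- vapply(adj[[v]], function(w) paste(leaves_of(w), collapse = "|"),
                  character(1))
  paste(sort(parts), collapse = " / ")
}

# build an unrooted tree over leaves X realizing a compatible cluster set
# (clusters given as name vectors not containing the reference leaf)
tree_from_clusters <- function(X, clusters) {
  X <- sort(X)
  ref <- X[1L]
  clusters <- unique(lapply(clusters, function(s) sort(s)))
  keys <- vapply(clusters, paste, character(1), collapse = "|")
  clusters <- clusters[!duplicated(keys)]
  # drop trivial clusters (single leaves / all non-ref leaves)
  clusters <- Filter(function(s) length(s) >= 2L &&
                       length(s) < length(X) - 0L &&
                       !(ref %in% s) && length(setdiff(X, s)) >= 2L,
                     clusters)
  sizes <- vapply(clusters, length, integer(1))
  ord <- order(sizes, decreasing = TRUE)
  clusters <- clusters[ord]
  nc <- length(clusters)
  # parent of each cluster: smallest strictly containing cluster (else root)
  nv <- 1L + nc + length(X)
  vnames <- c("", rep("", nc), X)
  leaf <- c(FALSE, rep(FALSE, nc), rep(TRUE, length(X)))
  cl_v <- if (nc) 1L + seq_len(nc) else integer(0)
  leaf_v <- 1L + nc + seq_along(X)
  edges <- matrix(integer(0), ncol = 2)
  parent_of_cluster <- rep(1L, nc)
  if (nc > 1L) {
    for (i in seq_len(nc)) {
      best <- 0L; bsize <- Inf
      for (j in seq_len(nc)) {
        if (i == j) next
        if (all(clusters[[i]] %in% clusters[[j]]) &&
            length(clusters[[j]]) > length(clusters[[i]])) {
          if (length(clusters[[j]]) < bsize) {
            bsize <- length(clusters[[j]]); best <- j
          }
        }
      }
      if (best > 0L) parent_of_cluster[i] <- cl_v[best]
    }
  }
  for (i in seq_len(nc)) edges <- rbind(edges, c(parent_of_cluster[i], cl_v[i]))
  for (k in seq_along(X)) {
    nm <- X[k]
    if (nm == ref) { edges <- rbind(edges, c(1L, leaf_v[k])); next }
    best <- 0L; bsize <- Inf
    for (j in seq_len(nc)) {
      if (nm %in% clusters[[j]] && length(clusters[[j]]) < bsize) {
        bsize <- length(clusters[[j]]); best <- j
      }
    }
    edges <- rbind(edges,
                   c(if (best > 0L) cl_v[best] else 1L, leaf_v[k]))
  }
  tr <- lt_make(edges, vector("list", nv), vnames, leaf)
  tr <- lt_suppress2_tracked(tr)
  attr(tr, "edge_src") <- NULL
  attr(tr, "vertex_src") <- NULL
  tr
}

# extract the induced subtree on a vertex set (must be connected)
lt_induced <- function(tr, vids) {
  dr <- lt_drop_vertices(tr, setdiff(seq_len(lt_nv(tr)), vids))
  list(tree = dr$tree, vmap = dr$vmap)
}

#' Merge the trees of two overlapping disks
#'
#' Collapses conflicting overlap edges in both trees, glues them through
#' a backbone realizing the union of the remaining overlap splits, then
#' expands every multifurcation into all binary resolutions (capped at
#' `max_candidates`), scores every candidate and returns the most
#' parsimonious.
#'
#' @param t0,t1 fully labeled trees sharing exactly the overlap leaves.
#' @param overlap character vector of shared genome names.
#' @param params [dcm_params()].
#' @param cache optional median cache environment.
#' @return a `scored_topology` with attribute `candidates`.
#' @export
merge_overlapping <- function(t0, t1, overlap, params = dcm_params(),
                              cache = NULL) {
  if (is.null(cache)) cache <- new.env(hash = TRUE, parent = emptyenv())
  tt0 <- as_lt(t0); tt1 <- as_lt(t1)
  X <- sort(overlap)
  if (length(X) == 0L) stop("empty overlap: use merge_nonoverlapping")
  if (!all(X %in% leaf_names(tt0)) || !all(X %in% leaf_names(tt1))) {
    stop("overlap genomes must be leaves of both trees")
  }

  if (length(X) == 1L) {
    M <- merge_single_overlap(tt0, tt1, X)
    cands <- list(M)
  } else {
    conf <- conflicting_overlap_edges(tt0, tt1, X)
    t0c <- if (length(conf$edges0)) lt_contract(tt0, conf$edges0)$tree else tt0
    t1c <- if (length(conf$edges1)) lt_contract(tt1, conf$edges1)$tree else tt1
    M <- glue_overlap(t0c, t1c, X)
    cands <- lt_enumerate_resolutions(M, params$max_candidates)
  }

  best <- NULL; best_score <- Inf; n_cand <- 0L; ties <- list()
  for (cand in cands) {
    cand <- lt_fill_labels(cand, cache, params$median_budget)
    st <- score_topology(cand, params$max_passes, params$median_budget,
                         cache)
    n_cand <- n_cand + 1L
    if (st$score < best_score) {
      best <- st; best_score <- st$score; ties <- list(st)
    } else if (st$score == best_score) {
      ties[[length(ties) + 1L]] <- st
      if (n_supported_edges(st$tree) < n_supported_edges(best$tree)) {
        best <- st
      }
    }
  }
  attr(best, "candidates") <- n_cand
  attr(best, "ties") <- ties
  best
}

# number of internal edges with positive realized length
n_supported_edges <- function(tr) {
  if (nrow(tr$edges) == 0L) return(0L)
  sum(!tr$leaf[tr$edges[, 1L]] & !tr$leaf[tr$edges[, 2L]] &
        !is.na(tr$lengths) & tr$lengths > 0)
}

# single shared genome: subdivide its pendant edge in t0 and bridge to its
# former neighbor in t1 (the duplicate leaf removed)
merge_single_overlap <- function(tt0, tt1, X) {
  z1 <- which(tt1$leaf & tt1$vnames == X)
  p1 <- setdiff(tt1$edges[which(tt1$edges[, 1L] == z1 |
                                  tt1$edges[, 2L] == z1), ], z1)
  dr <- lt_drop_vertices(tt1, z1)
  t1r <- dr$tree
  p1r <- dr$vmap[p1]
  un <- lt_union(tt0, t1r)
  tr <- un$tree
  z0 <- which(tt0$leaf & tt0$vnames == X)
  if (nrow(tt0$edges) == 0L) {
    # t0 is the single shared genome: t1 already contains the structure
    x0 <- z0
  } else {
    e0 <- which(tt0$edges[, 1L] == z0 | tt0$edges[, 2L] == z0)[1L]
    sd <- lt_subdivide(tr, e0)
    tr <- sd$tree
    tr$labels[[sd$v]] <- tt0$labels[[z0]]
    x0 <- sd$v
  }
  lt_add_edge(tr, x0, p1r + un$offset)
}

# glue two (possibly multifurcating) trees sharing the overlap leaves X
glue_overlap <- function(t0c, t1c, X) {
  r0 <- lt_restrict(t0c, X); r1 <- lt_restrict(t1c, X)
  sides_r <- function(r) {
    if (nrow(r$edges) == 0L) return(list())
    lapply(seq_len(nrow(r$edges)), function(k) {
      side <- lt_side_of(r, k, r$edges[k, 1L])
      r$vnames[intersect(side, which(r$leaf))]
    })
  }
  s0 <- sides_r(r0); s1 <- sides_r(r1)
  cl0 <- lapply(s0, function(s) setdiff_ref(s, X))
  cl1 <- lapply(s1, function(s) setdiff_ref(s, X))
  # defensive: drop residual incompatibilities from t1's side
  ok1 <- vapply(cl1, function(s) {
    all(!vapply(cl0, function(a) splits_incompatible(a, s, X), logical(1)))
  }, logical(1))
  B <- tree_from_clusters(X, c(cl0, cl1[ok1]))
  # leaf labels for X from t0
  for (nm in X) {
    vB <- which(B$leaf & B$vnames == nm)
    v0 <- which(t0c$leaf & t0c$vnames == nm)
    B$labels[[vB]] <- t0c$labels[[v0]]
  }
  Bsplit <- vapply(seq_len(nrow(B$edges)), function(k) {
    side <- lt_side_of(B, k, B$edges[k, 1L])
    canon_split(B$vnames[intersect(side, which(B$leaf))], X)
  }, character(1))

  # collect attachments from both trees:
  #  path pieces keyed by backbone edge split; vertex pieces keyed by
  #  backbone vertex id
  edge_att <- list()   # split -> list of list(tree=, piece=, ord=, side=)
  vert_att <- list()   # as list of list(vB=, tree=, piece=)
  for (side_id in 1:2) {
    tc <- if (side_id == 1L) t0c else t1c
    rc <- if (side_id == 1L) r0 else r1
    si <- lt_steiner_info(tc, X)
    if (length(si$pieces) == 0L) next
    rsplits <- vapply(seq_len(nrow(rc$edges)), function(k) {
      side <- lt_side_of(rc, k, rc$edges[k, 1L])
      canon_split(rc$vnames[intersect(side, which(rc$leaf))], X)
    }, character(1))
    # original tc edge id -> rc edge id
    e2r <- integer(0)
    es <- attr(rc, "edge_src")
    for (k in seq_along(es)) e2r[as.character(es[[k]])] <- k
    vsrc <- attr(rc, "vertex_src")
    # path order: position of each steiner vertex along its rc edge
    for (pc in si$pieces) {
      va <- pc$va
      if (si$sdeg[va] == 2L) {
        # on a suppressed path: find the rc edge through va
        ke <- which((tc$edges[, 1L] == va | tc$edges[, 2L] == va))
        ke <- ke[vapply(ke, function(k) {
          a <- tc$edges[k, 1L]; b <- tc$edges[k, 2L]
          si$alive[a] && si$alive[b]
        }, logical(1))]
        rk <- e2r[as.character(ke[1L])]
        spl <- rsplits[rk]
        ordv <- path_position(tc, rc, rk, va, X)
        edge_att[[length(edge_att) + 1L]] <-
          list(split = spl, tree = side_id, piece = pc, ord = ordv)
      } else {
        # at a retained (branch) vertex: map through the vertex signature
        vr <- which(vsrc == va)
        sig <- vertex_signature(rc, vr)
        vB <- match_backbone_vertex(B, Bsplit, rsplits, sig, X)
        vert_att[[length(vert_att) + 1L]] <-
          list(vB = vB, tree = side_id, piece = pc, va_label = tc$labels[[va]])
      }
    }
  }

  M <- B
  # vertex attachments first (they do not disturb edge identity by split)
  for (at in vert_att) {
    tc <- if (at$tree == 1L) t0c else t1c
    ind <- lt_induced(tc, at$piece$vertices)
    un <- lt_union(M, ind$tree)
    M <- un$tree
    if (is.null(M$labels[[at$vB]])) M$labels[[at$vB]] <- at$va_label
    M <- lt_add_edge(M, at$vB, ind$vmap[at$piece$pb] + un$offset)
  }
  # path attachments: chain per backbone edge, t0's pieces first (each in
  # its own subdividing vertex, ordered along the path)
  if (length(edge_att)) {
    keys <- vapply(edge_att, function(a) a$split, character(1))
    for (spl in unique(keys)) {
      grp <- edge_att[keys == spl]
      ordv <- order(vapply(grp, function(a) a$tree, integer(1)),
                    vapply(grp, function(a) a$ord, numeric(1)))
      grp <- grp[ordv]
      k <- resolve_backbone_edge(M, spl, X)
      prev <- M$edges[k, 1L]
      last <- M$edges[k, 2L]
      # orient: prev = endpoint on the reference-leaf side
      if (!ref_side_first(M, k, X)) { tmp <- prev; prev <- last; last <- tmp }
      # remove edge k, rebuild
      keep_e <- setdiff(seq_len(nrow(M$edges)), k)
      M$edges <- M$edges[keep_e, , drop = FALSE]
      if (!is.null(M$lengths)) M$lengths <- M$lengths[keep_e]
      both_trees <- length(unique(vapply(grp, function(a) a$tree,
                                         integer(1)))) > 1L
      if (both_trees) {
        # pieces from both trees share this path: their relative order is
        # not determined by either sub-topology. One multifurcating vertex
        # collects them; resolution enumeration explores the placements.
        M2 <- lt_subdivide_free(
          M, (if (grp[[1L]]$tree == 1L) t0c else t1c)$labels[[grp[[1L]]$piece$va]])
        M <- M2$tree; w <- M2$v
        M <- lt_add_edge(M, prev, w)
        for (at in grp) {
          tc <- if (at$tree == 1L) t0c else t1c
          ind <- lt_induced(tc, at$piece$vertices)
          un <- lt_union(M, ind$tree)
          M <- un$tree
          M <- lt_add_edge(M, w, ind$vmap[at$piece$pb] + un$offset)
        }
        M <- lt_add_edge(M, w, last)
      } else {
        # single source tree: its path order is part of the sub-topology
        # and is preserved as a chain
        cur <- prev
        done_va <- list()
        for (at in grp) {
          tc <- if (at$tree == 1L) t0c else t1c
          va_key <- paste(at$tree, at$piece$va)
          if (!is.null(done_va[[va_key]])) {
            w <- done_va[[va_key]]
          } else {
            M2 <- lt_subdivide_free(M, tc$labels[[at$piece$va]])
            M <- M2$tree; w <- M2$v
            M <- lt_add_edge(M, cur, w)
            cur <- w
            done_va[[va_key]] <- w
          }
          ind <- lt_induced(tc, at$piece$vertices)
          un <- lt_union(M, ind$tree)
          M <- un$tree
          M <- lt_add_edge(M, w, ind$vmap[at$piece$pb] + un$offset)
        }
        M <- lt_add_edge(M, cur, last)
      }
    }
  }
  M
}

# 1-based position of steiner vertex va along the suppressed path of
# restricted edge rk, counted from the path endpoint on the reference
# leaf's side (fixes the chain order deterministically)
path_position <- function(tc, rc, rk, va, X) {
  es <- attr(rc, "edge_src")[[rk]]
  vsrc <- attr(rc, "vertex_src")
  aend <- vsrc[rc$edges[rk, 1L]]
  bend <- vsrc[rc$edges[rk, 2L]]
  ref <- sort(X)[1L]
  side <- lt_side_of(rc, rk, rc$edges[rk, 1L])
  nm <- rc$vnames[intersect(side, which(rc$leaf))]
  start <- if (ref %in% nm) aend else bend
  stopv <- if (start == aend) bend else aend
  # walk the path using only the source edges
  pos <- 0L
  cur <- start
  prev <- -1L
  repeat {
    pos <- pos + 1L
    if (cur == va) return(pos)
    if (cur == stopv && pos > 1L) break
    nxt <- NA_integer_
    for (k in es) {
      a <- tc$edges[k, 1L]; b <- tc$edges[k, 2L]
      if (a == cur && b != prev) { nxt <- b; break }
      if (b == cur && a != prev) { nxt <- a; break }
    }
    if (is.na(nxt)) break
    prev <- cur
    cur <- nxt
  }
  stop("path walk failed for overlap merge")
}

setdiff_ref <- function(side, X) {
  ref <- sort(X)[1L]
  if (ref %in% side) setdiff(X, side) else side
}

# append a free unlabeled internal vertex carrying an optional label
lt_subdivide_free <- function(tr, label = NULL) {
  w <- lt_nv(tr) + 1L
  length(tr$labels) <- w
  tr$labels[[w]] <- label
  tr$vnames <- c(tr$vnames, "")
  tr$leaf <- c(tr$leaf, FALSE)
  list(tree = tr, v = w)
}

# id of the backbone edge whose X-split matches `spl`
resolve_backbone_edge <- function(M, spl, X) {
  for (k in seq_len(nrow(M$edges))) {
    side <- lt_side_of(M, k, M$edges[k, 1L])
    nm <- M$vnames[intersect(side, which(M$leaf))]
    nm <- nm[nm %in% X]
    if (canon_split(nm, X) == spl) return(k)
  }
  stop("backbone edge not found for split ", spl)
}

# TRUE when endpoint 1 of edge k lies on the side containing the
# reference leaf of X
ref_side_first <- function(M, k, X) {
  ref <- sort(X)[1L]
  side <- lt_side_of(M, k, M$edges[k, 1L])
  nm <- M$vnames[intersect(side, which(M$leaf))]
  ref %in% nm
}

# map an rc vertex signature onto the backbone: contract backbone edges
# whose splits are absent from the restricted tree, then match partition
# signatures; the representative is the lowest backbone vertex id
match_backbone_vertex <- function(B, Bsplit, rsplits, sig, X) {
  drop_e <- which(!(Bsplit %in% rsplits) &
                    !B$leaf[B$edges[, 1L]] & !B$leaf[B$edges[, 2L]])
  if (length(drop_e) == 0L) {
    Bc <- B; vmap <- seq_len(lt_nv(B))
  } else {
    ct <- lt_contract(B, drop_e)
    Bc <- ct$tree; vmap <- ct$vmap
  }
  for (v in which(!Bc$leaf)) {
    if (vertex_signature(Bc, v) == sig) {
      return(min(which(vmap == v)))
    }
  }
  stop("backbone vertex match failed")
}

# fill missing labels: vertices with the most labeled neighbors first;
# three labeled neighbors give the inversion median, otherwise the lowest
# numbered labeled neighbor's genome is copied
lt_fill_labels <- function(tr, cache, budget) {
  repeat {
    unl <- which(vapply(tr$labels, is.null, logical(1)))
    if (length(unl) == 0L) break
    adj <- lt_adj(tr)
    nlab <- vapply(unl, function(v) {
      sum(!vapply(tr$labels[adj[[v]]], is.null, logical(1)))
    }, integer(1))
    if (max(nlab) == 0L) stop("cannot fill labels: no labeled neighbor")
    v <- unl[which.max(nlab)]
    labs <- adj[[v]][!vapply(tr$labels[adj[[v]]], is.null, logical(1))]
    if (length(labs) >= 3L) {
      tr$labels[[v]] <- median3(cache, tr$labels[[labs[1L]]],
                                tr$labels[[labs[2L]]],
                                tr$labels[[labs[3L]]], budget)$median
    } else {
      tr$labels[[v]] <- tr$labels[[labs[1L]]]
    }
  }
  tr
}
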