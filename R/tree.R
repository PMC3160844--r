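# Unrooted trees whose leaves AND internal vertices can carry genome
# labels. Vertices are integer ids 1..V; edges an m x 2 matrix. The
# parsimony score of a fully labeled tree is the sum over edges of the
# inversion distance between endpoint labels.

lt_make <- function(edges, labels, vnames, leaf, lengths = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  nv <- length(labels)
  tr <- structure(list(edges = edges, lengths = lengths, labels = labels,
                       vnames = as.character(vnames),
                       leaf = as.logical(leaf)),
                  class = "labeled_tree")
  if (nv >= 2L && nrow(edges) != nv - 1L) {
    stop("labeled_tree must be a tree: ", nrow(edges), " edges for ",
         nv, " vertices")
  }
  tr
}

lt_nv <- function(tr) length(tr$labels)

lt_adj <- function(tr) {
  nv <- lt_nv(tr)
  adj <- vector("list", nv)
  if (nrow(tr$edges) == 0L) return(adj)
  for (k in seq_len(nrow(tr$edges))) {
    a <- tr$edges[k, 1L]; b <- tr$edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

lt_degree <- function(tr) {
  tabulate(tr$edges, nbins = lt_nv(tr))
}

leaf_names <- function(tr) sort(tr$vnames[tr$leaf])

#' @export
print.labeled_tree <- function(x, ...) {
  cat("labeled_tree:", sum(x$leaf), "leaves,", lt_nv(x), "vertices",
      if (all(!vapply(x$labels, is.null, logical(1)))) "(fully labeled)"
      else "", "\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

# single-vertex tree holding one genome
lt_single <- function(genes, name) {
  lt_make(matrix(integer(0), ncol = 2), list(as.integer(genes)), name, TRUE)
}

#' Parsimony score of a fully labeled tree
#'
#' @param tree a fully labeled `labeled_tree`.
#' @return the sum over edges of the inversion distance between endpoint
#'   labels.
#' @export
tree_score <- function(tree) {
  if (any(vapply(tree$labels, is.null, logical(1)))) {
    stop("tree_score requires every vertex to carry a genome label")
  }
  if (nrow(tree$edges) == 0L) return(0L)
  sum(vapply(seq_len(nrow(tree$edges)), function(k) {
    cpp_inv_dist(tree$labels[[tree$edges[k, 1L]]],
                 tree$labels[[tree$edges[k, 2L]]])
  }, integer(1)))
}

# set per-edge lengths from endpoint label distances
lt_set_lengths_from_labels <- function(tr) {
  if (nrow(tr$edges) == 0L) { tr$lengths <- numeric(0); return(tr) }
  tr$lengths <- vapply(seq_len(nrow(tr$edges)), function(k) {
    as.numeric(cpp_inv_dist(tr$labels[[tr$edges[k, 1L]]],
                            tr$labels[[tr$edges[k, 2L]]]))
  }, numeric(1))
  tr
}

# --- traversal -------------------------------------------------------------

# vertices of the component containing `start` after removing edge k
lt_side_of <- function(tr, k, start) {
  adj <- lt_adj(tr)
  a <- tr$edges[k, 1L]; b <- tr$edges[k, 2L]
  seen <- logical(lt_nv(tr))
  seen[start] <- TRUE
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if ((v == a && w == b) || (v == b && w == a)) next
      if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
    }
  }
  which(seen)
}

# canonical string for the bipartition of the leaf set induced by edge k
lt_split_of_edge <- function(tr, k, all_leaves = NULL) {
  if (is.null(all_leaves)) all_leaves <- leaf_names(tr)
  ref <- all_leaves[1L]
  side <- lt_side_of(tr, k, tr$edges[k, 1L])
  nm <- tr$vnames[intersect(side, which(tr$leaf))]
  if (ref %in% nm) nm <- setdiff(all_leaves, nm)
  paste(sort(nm), collapse = "|")
}

# splits of all internal edges (both endpoints non-leaf)
lt_internal_splits <- function(tr) {
  if (nrow(tr$edges) == 0L) return(character(0))
  al <- leaf_names(tr)
  internal <- which(!tr$leaf[tr$edges[, 1L]] & !tr$leaf[tr$edges[, 2L]])
  vapply(internal, function(k) lt_split_of_edge(tr, k, al), character(1))
}

# --- surgery ---------------------------------------------------------------

# append an unlabeled internal vertex in the middle of edge k
lt_subdivide <- function(tr, k) {
  nv <- lt_nv(tr)
  w <- nv + 1L
  a <- tr$edges[k, 1L]; b <- tr$edges[k, 2L]
  tr$labels[[w]] <- NULL; length(tr$labels) <- w
  tr$vnames <- c(tr$vnames, "")
  tr$leaf <- c(tr$leaf, FALSE)
  tr$edges[k, ] <- c(a, w)
  tr$edges <- rbind(tr$edges, c(w, b))
  if (!is.null(tr$lengths)) tr$lengths <- c(tr$lengths, NA_real_)
  list(tree = tr, v = w)
}

# disjoint union of two trees; returns combined tree and the id offset of t1
lt_union <- function(t0, t1) {
  off <- lt_nv(t0)
  edges <- rbind(t0$edges, t1$edges + off)
  labels <- c(t0$labels, t1$labels)
  vnames <- c(t0$vnames, t1$vnames)
  leaf <- c(t0$leaf, t1$leaf)
  lengths <- if (!is.null(t0$lengths) && !is.null(t1$lengths)) {
    c(t0$lengths, t1$lengths)
  } else NULL
  list(tree = structure(list(edges = edges, lengths = lengths,
                             labels = labels, vnames = vnames, leaf = leaf),
                        class = "labeled_tree"),
       offset = off)
}

lt_add_edge <- function(tr, a, b) {
  tr$edges <- rbind(tr$edges, c(a, b))
  if (!is.null(tr$lengths)) tr$lengths <- c(tr$lengths, NA_real_)
  tr
}

# contract the given edges (ids); endpoints merge into the lower-id vertex.
# Labels: the surviving vertex keeps its own label. Returns tree + vertex map.
lt_contract <- function(tr, eidx) {
  nv <- lt_nv(tr)
  parent <- seq_len(nv)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in eidx) {
    a <- findp(tr$edges[k, 1L]); b <- findp(tr$edges[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nv), findp, integer(1))
  keep <- sort(unique(root))
  newid <- integer(nv); newid[keep] <- seq_along(keep)
  vmap <- newid[root]
  edges <- tr$edges[setdiff(seq_len(nrow(tr$edges)), eidx), , drop = FALSE]
  edges2 <- cbind(vmap[edges[, 1L]], vmap[edges[, 2L]])
  lens <- if (!is.null(tr$lengths)) {
    tr$lengths[setdiff(seq_len(nrow(tr$edges)), eidx)]
  } else NULL
  list(tree = structure(list(edges = edges2, lengths = lens,
                             labels = tr$labels[keep],
                             vnames = tr$vnames[keep],
                             leaf = tr$leaf[keep]),
                        class = "labeled_tree"),
       vmap = vmap)
}

# drop vertices (and incident edges), re-indexing the rest; returns map
lt_drop_vertices <- function(tr, drop) {
  keep <- setdiff(seq_len(lt_nv(tr)), drop)
  newid <- integer(lt_nv(tr)); newid[keep] <- seq_along(keep)
  sel <- !(tr$edges[, 1L] %in% drop | tr$edges[, 2L] %in% drop)
  edges <- tr$edges[sel, , drop = FALSE]
  list(tree = structure(list(
    edges = cbind(newid[edges[, 1L]], newid[edges[, 2L]]),
    lengths = if (!is.null(tr$lengths)) tr$lengths[sel] else NULL,
    labels = tr$labels[keep], vnames = tr$vnames[keep],
    leaf = tr$leaf[keep]), class = "labeled_tree"),
    vmap = newid)
}

# restriction of a tree to a subset of its leaves (Steiner subtree with
# degree-2 vertices suppressed). Tracks, per restricted edge, the original
# edge ids it covers (attr "edge_src") and original vertex ids
# (attr "vertex_src").
lt_restrict <- function(tr, keep_names) {
  keepv <- which(tr$leaf & tr$vnames %in% keep_names)
  if (length(keepv) != length(keep_names)) {
    stop("restriction names missing from tree")
  }
  # prune non-kept leaves iteratively
  cur <- tr
  attr(cur, "edge_src") <- as.list(seq_len(nrow(cur$edges)))
  attr(cur, "vertex_src") <- seq_len(lt_nv(cur))
  repeat {
    deg <- lt_degree(cur)
    vsrc <- attr(cur, "vertex_src")
    drop <- which(deg <= 1L &
                    !(cur$leaf & cur$vnames %in% keep_names))
    drop <- drop[deg[drop] <= 1L]
    if (length(drop) == 0L) break
    es <- attr(cur, "edge_src")
    sel <- !(cur$edges[, 1L] %in% drop | cur$edges[, 2L] %in% drop)
    dr <- lt_drop_vertices(cur, drop)
    cur <- dr$tree
    attr(cur, "edge_src") <- es[sel]
    attr(cur, "vertex_src") <- vsrc[setdiff(seq_along(vsrc), drop)]
  }
  # non-kept leaves are gone; mark kept leaves only
  cur$leaf <- cur$leaf & cur$vnames %in% keep_names
  lt_suppress2_tracked(cur)
}

# suppress degree-2 vertices while maintaining edge_src and vertex_src
lt_suppress2_tracked <- function(tr) {
  if (is.null(attr(tr, "edge_src"))) {
    attr(tr, "edge_src") <- as.list(seq_len(nrow(tr$edges)))
  }
  if (is.null(attr(tr, "vertex_src"))) {
    attr(tr, "vertex_src") <- seq_len(lt_nv(tr))
  }
  repeat {
    deg <- lt_degree(tr)
    v <- which(!tr$leaf & deg == 2L)
    if (length(v) == 0L) break
    v <- v[1L]
    es <- attr(tr, "edge_src")
    vsrc <- attr(tr, "vertex_src")
    ks <- which(tr$edges[, 1L] == v | tr$edges[, 2L] == v)
    a <- setdiff(tr$edges[ks[1L], ], v)
    b <- setdiff(tr$edges[ks[2L], ], v)
    src <- c(es[[ks[1L]]], es[[ks[2L]]])
    len <- if (!is.null(tr$lengths)) sum(tr$lengths[ks]) else NULL
    keep_e <- setdiff(seq_len(nrow(tr$edges)), ks)
    tr$edges <- rbind(tr$edges[keep_e, , drop = FALSE], c(a, b))
    if (!is.null(tr$lengths)) tr$lengths <- c(tr$lengths[keep_e], len)
    es <- c(es[keep_e], list(src))
    # drop v
    keep <- setdiff(seq_len(lt_nv(tr)), v)
    newid <- integer(lt_nv(tr)); newid[keep] <- seq_along(keep)
    tr <- structure(list(
      edges = cbind(newid[tr$edges[, 1L]], newid[tr$edges[, 2L]]),
      lengths = tr$lengths, labels = tr$labels[keep],
      vnames = tr$vnames[keep], leaf = tr$leaf[keep]),
      class = "labeled_tree")
    attr(tr, "edge_src") <- es
    attr(tr, "vertex_src") <- vsrc[keep]
  }
  tr
}

# --- multifurcation resolution --------------------------------------------

# all unrooted binary topologies on k labeled stubs, as edge lists over
# vertices 1..k (stubs) and k+1.. (internal); generated by sequential
# insertion so the enumeration order is deterministic
resolutions_of_degree <- function(k) {
  if (k == 3L) {
    return(list(matrix(c(1L, 4L, 2L, 4L, 3L, 4L), ncol = 2, byrow = TRUE)))
  }
  prev <- resolutions_of_degree(k - 1L)
  out <- list()
  for (tr in prev) {
    # shift parent's internal ids (> k-1) up by one so stub k is free
    m0 <- ifelse(tr > k - 1L, tr + 1L, tr)
    w <- 2L * k - 2L
    for (e in seq_len(nrow(m0))) {
      m <- m0
      a <- m[e, 1L]; b <- m[e, 2L]
      m[e, ] <- c(a, w)
      m <- rbind(m, c(w, b), c(k, w))
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

# replace multifurcating vertex v by each binary resolution of its k
# neighbor stubs; returns a list of trees (enumeration order fixed)
lt_resolve_vertex <- function(tr, v) {
  adj <- lt_adj(tr)
  nbs <- adj[[v]]
  k <- length(nbs)
  if (k <= 3L) return(list(tr))
  # edge ids to each neighbor (parallel edges impossible in a tree)
  eid <- vapply(nbs, function(w) {
    which((tr$edges[, 1L] == v & tr$edges[, 2L] == w) |
          (tr$edges[, 2L] == v & tr$edges[, 1L] == w))[1L]
  }, integer(1))
  res <- resolutions_of_degree(k)
  lapply(res, function(m) {
    # vertices 1..k are stubs -> neighbors; k+1..2k-2 internal -> new ids;
    # reuse v as the first internal vertex, append the other k-3
    n_int <- k - 2L
    base <- lt_nv(tr)
    int_ids <- c(v, if (n_int > 1L) base + seq_len(n_int - 1L) else integer(0))
    t2 <- tr
    if (n_int > 1L) {
      length(t2$labels) <- base + n_int - 1L
      t2$vnames <- c(t2$vnames, rep("", n_int - 1L))
      t2$leaf <- c(t2$leaf, rep(FALSE, n_int - 1L))
    }
    # drop old star edges, add resolution edges
    keep_e <- setdiff(seq_len(nrow(t2$edges)), eid)
    lens <- if (!is.null(t2$lengths)) t2$lengths[keep_e] else NULL
    edges <- t2$edges[keep_e, , drop = FALSE]
    vid <- function(x) if (x <= k) nbs[x] else int_ids[x - k]
    for (r in seq_len(nrow(m))) {
      edges <- rbind(edges, c(vid(m[r, 1L]), vid(m[r, 2L])))
      if (!is.null(lens)) lens <- c(lens, NA_real_)
    }
    t2$edges <- edges
    t2$lengths <- lens
    t2
  })
}

# enumerate binary resolutions of every multifurcation, combined
# multiplicatively, capped at max_candidates (with a warning when truncated)
lt_enumerate_resolutions <- function(tr, max_candidates = 10000L) {
  out <- list(tr)
  truncated <- FALSE
  repeat {
    deg <- lt_degree(out[[1L]])
    v <- which(!out[[1L]]$leaf & deg > 3L)
    if (length(v) == 0L) break
    v <- v[1L]
    nxt <- list()
    for (t in out) {
      rs <- lt_resolve_vertex(t, v)
      for (r in rs) {
        if (length(nxt) >= max_candidates) { truncated <- TRUE; break }
        nxt[[length(nxt) + 1L]] <- r
      }
      if (truncated) break
    }
    out <- nxt
    if (truncated) break
  }
  if (truncated) {
    warning("resolution enumeration truncated at ", max_candidates,
            " candidates")
  }
  attr(out, "truncated") <- truncated
  out
}

# --- Newick I/O ------------------------------------------------------------

#' Read a Newick tree
#'
#' Parses standard Newick (via \pkg{ape}) into a `labeled_tree`; leaf
#' names and branch lengths are preserved. Genome labels are not carried
#' by Newick and are left unset.
#'
#' @param path file path, or `text` for an inline string.
#' @param text optional Newick string.
#' @return a `labeled_tree`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  ph <- if (!is.null(text)) ape::read.tree(text = text)
  else ape::read.tree(path)
  if (is.null(ph)) stop("Newick parse error")
  if (anyDuplicated(ph$tip.label)) stop("duplicate leaf names in Newick")
  tr <- lt_from_phylo(ph)
  # a rooting artifact (degree-2 internal vertex) carries no topology;
  # suppress it so "(A,B);" reads as a single edge
  tr <- lt_suppress2_tracked(tr)
  attr(tr, "edge_src") <- NULL
  attr(tr, "vertex_src") <- NULL
  tr
}

lt_from_phylo <- function(ph) {
  ntip <- length(ph$tip.label)
  nv <- ntip + ph$Nnode
  vnames <- c(ph$tip.label,
              if (!is.null(ph$node.label)) ph$node.label
              else rep("", ph$Nnode))
  vnames[is.na(vnames)] <- ""
  lt_make(ph$edge, vector("list", nv), vnames,
          c(rep(TRUE, ntip), rep(FALSE, ph$Nnode)),
          lengths = ph$edge.length)
}

#' Write a tree as Newick
#'
#' @param tree a `labeled_tree`.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @param digits digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  nv <- lt_nv(tree)
  if (nv == 1L) {
    txt <- paste0(tree$vnames[1L], ";")
  } else if (nv == 2L) {
    l1 <- if (!is.null(tree$lengths) && !is.na(tree$lengths[1L])) {
      paste0(":", format(tree$lengths[1L], digits = digits))
    } else ""
    txt <- paste0("(", tree$vnames[1L], l1, ",", tree$vnames[2L], ");")
  } else {
    root <- which(!tree$leaf)[1L]
    if (is.na(root)) root <- 1L  # two-leaf tree
    adj <- lt_adj(tree)
    elen <- function(a, b) {
      if (is.null(tree$lengths)) return("")
      k <- which((tree$edges[, 1L] == a & tree$edges[, 2L] == b) |
                 (tree$edges[, 2L] == a & tree$edges[, 1L] == b))[1L]
      l <- tree$lengths[k]
      if (is.na(l)) "" else paste0(":", format(l, digits = digits))
    }
    rec <- function(v, from) {
      kids <- setdiff(adj[[v]], from)
      if (length(kids) == 0L) return(tree$vnames[v])
      inner <- paste(vapply(kids, function(w) {
        paste0(rec(w, v), elen(v, w))
      }, character(1)), collapse = ",")
      paste0("(", inner, ")", if (!tree$leaf[v]) "" else tree$vnames[v])
    }
    txt <- paste0(rec(root, NA), ";")
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
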