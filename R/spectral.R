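# The spectral disk-covering method: Gaussian similarity over pairwise
# inversion distances, Fiedler vector of the random-walk Laplacian,
# overlap-aware bipartitioning with a big-overlap avoidance rewrite, and
# the recursive binary disk tree.

#' Parameters of the spectral disk-covering method
#'
#' @param alpha Gaussian similarity bandwidth as a fraction of the maximum
#'   pairwise distance in the disk (`sigma = alpha * d_max`); default
#'   0.125.
#' @param theta1 gap threshold triggering an overlapping decomposition;
#'   applied as `theta1 / sqrt(n)` for a disk of `n` genomes.
#' @param theta2 stop threshold for the outward overlap walk, applied as
#'   `theta2 / sqrt(n)`.
#' @param max_overlap_fraction cap on `|overlap| / |disk|`.
#' @param laplacian_kind `"random_walk"` (default), `"symmetric"` or
#'   `"unnormalized"`.
#' @param median_budget node budget for the exact inversion median search
#'   before it falls back to the greedy descent.
#' @param max_candidates cap on candidate trees enumerated when expanding
#'   collapsed edges in an overlapping merge.
#' @param max_passes maximum label-refinement passes when scoring a
#'   topology.
#' @param max_ties number of equal-parsimony sub-topologies carried
#'   upward through the recursive merge (the method can return several
#'   equally good trees; propagating ties lets a locally arbitrary
#'   choice be settled by the parent disk's score).
#' @return a `dcm_params` list.
#' @export
dcm_params <- function(alpha = 0.125, theta1 = 0.5, theta2 = 0.25,
                       max_overlap_fraction = 0.5,
                       laplacian_kind = c("random_walk", "symmetric",
                                          "unnormalized"),
                       median_budget = 20000L, max_candidates = 10000L,
                       max_passes = 50L, max_ties = 4L) {
  laplacian_kind <- match.arg(laplacian_kind)
  if (alpha <= 0) stop("alpha must be positive")
  if (theta2 <= 0 || theta2 > theta1) stop("need 0 < theta2 <= theta1")
  if (max_overlap_fraction < 0 || max_overlap_fraction > 1) {
    stop("max_overlap_fraction must be in [0, 1]")
  }
  structure(list(alpha = alpha, theta1 = theta1, theta2 = theta2,
                 max_overlap_fraction = max_overlap_fraction,
                 laplacian_kind = laplacian_kind,
                 median_budget = as.integer(median_budget),
                 max_candidates = as.integer(max_candidates),
                 max_passes = as.integer(max_passes),
                 max_ties = as.integer(max_ties)),
            class = "dcm_params")
}

#' Gaussian similarity context for a disk
#'
#' Builds the weighted adjacency matrix `w_ij = exp(-d_ij^2 / (2 sigma^2))`
#' with `sigma = alpha * d_max`, zero diagonal, and the degree vector.
#'
#' @param d distance matrix restricted to the disk (n >= 2).
#' @param alpha bandwidth fraction.
#' @return a `spectral_context` with `W`, `degree`, `sigma`, `d_max`.
#' @export
gaussian_similarity <- function(d, alpha = 0.125) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("disk must contain at least two genomes")
  d_max <- max(d)
  if (d_max == 0) {
    stop(structure(class = c("degenerate_disk", "error", "condition"),
                   list(message = "degenerate disk: all genomes identical",
                        call = sys.call(-1))))
  }
  sigma <- alpha * d_max
  W <- exp(-(d^2) / (2 * sigma^2))
  diag(W) <- 0
  structure(list(W = W, degree = rowSums(W), sigma = sigma, d_max = d_max),
            class = "spectral_context")
}

#' Graph Laplacian of a similarity context
#'
#' @param ctx a [gaussian_similarity()] context.
#' @param kind `"unnormalized"` (`D - W`), `"symmetric"`
#'   (`D^-1/2 (D - W) D^-1/2`) or `"random_walk"` (`D^-1 (D - W)`).
#' @return an `n x n` matrix.
#' @export
build_laplacian <- function(ctx, kind = c("random_walk", "symmetric",
                                          "unnormalized")) {
  kind <- match.arg(kind)
  if (any(ctx$degree <= 0)) {
    stop("degenerate disk: zero degree vertex")
  }
  L <- diag(ctx$degree) - ctx$W
  switch(kind,
    unnormalized = L,
    symmetric = {
      s <- 1 / sqrt(ctx$degree)
      t(L * s) * s   # D^-1/2 L D^-1/2 for symmetric L
    },
    random_walk = L / ctx$degree)
}

#' Fiedler vector of a disk
#'
#' The eigenvector for the second-smallest eigenvalue of the chosen
#' Laplacian. For the random-walk kind the symmetric Laplacian is solved
#' (deterministic dense symmetric eigensolver) and the eigenvector
#' transformed by `D^-1/2`, which maps between the two eigensystems at
#' equal eigenvalues. The vector is normalized to unit Euclidean norm with
#' the largest-magnitude entry positive (ties: lowest index).
#'
#' @inheritParams build_laplacian
#' @return a `fiedler_result` with `eigenvalue` and `vector`.
#' @export
fiedler_vector <- function(ctx, kind = c("random_walk", "symmetric",
                                         "unnormalized")) {
  kind <- match.arg(kind)
  solve_kind <- if (kind == "unnormalized") "unnormalized" else "symmetric"
  L <- build_laplacian(ctx, solve_kind)
  es <- eigen(L, symmetric = TRUE)
  n <- nrow(L)
  lambda <- es$values[n - 1L]
  v <- es$vectors[, n - 1L]
  if (kind == "random_walk") v <- v / sqrt(ctx$degree)
  v <- v / sqrt(sum(v^2))
  i0 <- which.max(abs(v))
  if (v[i0] < 0) v <- -v
  structure(list(eigenvalue = max(lambda, 0), vector = v),
            class = "fiedler_result")
}

#' Decompose a disk into two (possibly overlapping) child disks
#'
#' Sorts the genomes by Fiedler-vector entry; splits by sign; if the gap
#' between the smallest positive and largest negative entry is below
#' `theta1 / sqrt(n)`, walks outward from the boundary moving genomes into
#' the overlap until consecutive sorted entries differ by more than
#' `theta2 / sqrt(n)`; entries exactly zero go to the overlap. A
#' big-overlap avoidance rewrite ([avoid_large_overlap()]) is then
#' applied.
#'
#' @param disk integer vector of genome indices (rows of `d`), `|disk| >= 4`.
#' @param d full pairwise distance matrix.
#' @param params [dcm_params()].
#' @param avoid apply the big-overlap avoidance rewrite (internal recursion
#'   disables it).
#' @return a `disk_decomposition` with `parent`, `disk0`, `disk1`,
#'   `overlap` (index vectors) and diagnostics (`gap`, `eigenvalue`).
#' @export
decompose_disk <- function(disk, d, params = dcm_params(), avoid = TRUE) {
  n <- length(disk)
  if (n < 4L) stop("decompose_disk requires a disk of at least 4 genomes")
  sub <- d[disk, disk, drop = FALSE]
  if (max(sub) == 0) {
    # degenerate disk: arbitrary balanced split
    h <- n %/% 2L
    return(new_decomp(disk, disk[seq_len(h)], disk[(h + 1L):n], integer(0),
                      gap = NA_real_, eigenvalue = NA_real_,
                      degenerate = TRUE))
  }
  ctx <- gaussian_similarity(sub, params$alpha)
  fr <- fiedler_vector(ctx, params$laplacian_kind)
  v <- fr$vector
  thr1 <- params$theta1 / sqrt(n)
  thr2 <- params$theta2 / sqrt(n)
  ord <- order(v)          # stable: ties broken by input order
  vs <- v[ord]
  neg <- which(vs < 0); pos <- which(vs > 0); zer <- which(vs == 0)
  if (length(neg) == 0L || length(pos) == 0L) {
    # one sign class empty: split off the genome with the extreme entry
    ex <- ord[which.max(abs(vs))]
    dec <- new_decomp(disk, disk[ex], disk[setdiff(seq_len(n), ex)],
                      integer(0), gap = NA_real_,
                      eigenvalue = fr$eigenvalue, fallback = TRUE)
    return(dec)
  }
  gap <- vs[pos[1L]] - vs[neg[length(neg)]]
  ov <- zer
  if (gap < thr1 || length(zer) > 0L) {
    if (gap < thr1) {
      # walk outward on the negative side
      k <- length(neg)
      while (k >= 1L) {
        ov <- c(ov, neg[k])
        if (k == 1L) break
        if (vs[neg[k]] - vs[neg[k - 1L]] > thr2) break
        k <- k - 1L
      }
      # walk outward on the positive side
      k <- 1L
      while (k <= length(pos)) {
        ov <- c(ov, pos[k])
        if (k == length(pos)) break
        if (vs[pos[k + 1L]] - vs[pos[k]] > thr2) break
        k <- k + 1L
      }
    }
  }
  ov <- sort(unique(ov))
  # exclusive regions must stay non-empty: release outermost overlap
  # members on a side that was consumed entirely
  if (all(neg %in% ov)) ov <- setdiff(ov, neg[1L])
  if (all(pos %in% ov)) ov <- setdiff(ov, pos[length(pos)])
  # enforce the overlap cap, dropping the largest-magnitude entries first
  cap <- floor(params$max_overlap_fraction * n)
  if (length(ov) > cap) {
    drop_order <- ov[order(abs(vs[ov]), decreasing = TRUE)]
    ov <- setdiff(ov, drop_order[seq_len(length(ov) - cap)])
  }
  side0 <- union(setdiff(neg, ov), ov)
  side1 <- union(setdiff(c(pos, zer), ov), ov)
  dec <- new_decomp(disk, sort(disk[ord[side0]]), sort(disk[ord[side1]]),
                    sort(disk[ord[ov]]), gap = gap,
                    eigenvalue = fr$eigenvalue)
  if (avoid && length(dec$overlap) > 0L) {
    dec <- avoid_large_overlap(dec, d, params)
  }
  dec
}

new_decomp <- function(parent, disk0, disk1, overlap, gap = NA_real_,
                       eigenvalue = NA_real_, degenerate = FALSE,
                       fallback = FALSE) {
  structure(list(parent = sort(parent), disk0 = sort(disk0),
                 disk1 = sort(disk1), overlap = sort(overlap),
                 gap = gap, eigenvalue = eigenvalue,
                 degenerate = degenerate, fallback = fallback),
            class = "disk_decomposition")
}

#' @export
print.disk_decomposition <- function(x, ...) {
  cat("disk_decomposition: |parent| =", length(x$parent),
      "-> |disk0| =", length(x$disk0), ", |disk1| =", length(x$disk1),
      ", |overlap| =", length(x$overlap), "\n")
  invisible(x)
}

#' Rewrite a decomposition that placed too many genomes in the overlap
#'
#' Re-decomposes each child disk; if a child splits into two
#' non-overlapping disks, one of which holds the entire overlapping
#' region of the parent decomposition, the other child part (Disk 3) is
#' made one partition and all remaining genomes the other, yielding a
#' non-overlapping decomposition. Otherwise the input is returned
#' unchanged.
#'
#' @param decomp a `disk_decomposition` with non-empty overlap.
#' @param d full pairwise distance matrix.
#' @param params [dcm_params()].
#' @return a `disk_decomposition`.
#' @export
avoid_large_overlap <- function(decomp, d, params = dcm_params()) {
  if (length(decomp$overlap) == 0L) return(decomp)
  for (child in list(decomp$disk0, decomp$disk1)) {
    if (length(child) < 4L) next
    sub <- decompose_disk(child, d, params, avoid = FALSE)
    if (length(sub$overlap) > 0L) next
    for (pair in list(list(sub$disk0, sub$disk1),
                      list(sub$disk1, sub$disk0))) {
      disk2 <- pair[[1L]]; disk3 <- pair[[2L]]
      if (all(decomp$overlap %in% disk2) && length(disk3) > 0L) {
        rest <- setdiff(decomp$parent, disk3)
        if (length(rest) == 0L) next
        return(new_decomp(decomp$parent, disk3, rest, integer(0),
                          gap = decomp$gap, eigenvalue = decomp$eigenvalue))
      }
    }
  }
  decomp
}

#' Build the binary disk tree by recursive decomposition
#'
#' Recursively applies [decompose_disk()] until every disk holds three or
#' fewer genomes.
#'
#' @param d pairwise distance matrix for all genomes.
#' @param params [dcm_params()].
#' @param disk optional index subset (defaults to all genomes).
#' @return a `binary_disk_tree`: nested nodes with `disk`, and for
#'   internal nodes `decomp` plus `children`.
#' @export
build_disk_tree <- function(d, params = dcm_params(), disk = NULL) {
  if (is.null(disk)) disk <- seq_len(nrow(d))
  node <- build_disk_node(disk, d, params)
  class(node) <- c("binary_disk_tree", class(node))
  node
}

build_disk_node <- function(disk, d, params) {
  if (length(disk) <= 3L) {
    return(structure(list(disk = disk, decomp = NULL, children = NULL),
                     class = "disk_node"))
  }
  dec <- decompose_disk(disk, d, params)
  structure(list(disk = disk, decomp = dec,
                 children = list(build_disk_node(dec$disk0, d, params),
                                 build_disk_node(dec$disk1, d, params))),
            class = "disk_node")
}

#' @export
print.binary_disk_tree <- function(x, ...) {
  count <- function(nd) {
    if (is.null(nd$children)) return(c(1L, length(nd$disk)))
    a <- count(nd$children[[1L]]); b <- count(nd$children[[2L]])
    c(a[1L] + b[1L], max(a[2L], b[2L]))
  }
  cc <- count(x)
  cat("binary_disk_tree:", length(x$disk), "genomes,", cc[1L],
      "leaf disks\n")
  invisible(x)
}

# flatten all decompositions in a disk tree (for compatibility audits)
disk_tree_decompositions <- function(node) {
  if (is.null(node$children)) return(list())
  c(list(node$decomp),
    disk_tree_decompositions(node$children[[1L]]),
    disk_tree_decompositions(node$children[[2L]]))
}
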