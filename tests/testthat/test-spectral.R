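# Gaussian similarity, Laplacians, Fiedler vectors and the overlap-aware
# disk decomposition.

# additive distance matrix from a weighted tree described by merges
tree_metric <- function(newick) {
  tr <- read_newick(text = newick)
  nms <- sort(tr$vnames[tr$leaf])
  n <- length(nms)
  adj <- spectree:::lt_adj(tr)
  elen <- function(a, b) {
    k <- which((tr$edges[, 1] == a & tr$edges[, 2] == b) |
               (tr$edges[, 2] == a & tr$edges[, 1] == b))
    tr$lengths[k]
  }
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (s in which(tr$leaf)) {
    dist <- rep(NA_real_, length(tr$labels))
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + elen(v, w)
        queue <- c(queue, w)
      }
    }
    D[tr$vnames[s], ] <- dist[match(nms, tr$vnames)]
  }
  D
}

test_that("gaussian similarity has the stated form and bounds", {
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3)
  ctx <- gaussian_similarity(D, alpha = 0.125)
  expect_equal(ctx$sigma, 0.125 * 8)
  expect_equal(diag(ctx$W), rep(0, 3))
  # at d = d_max the weight is exp(-32) for alpha = 0.125
  expect_equal(ctx$W[1, 3], exp(-32))
  # monotone decreasing in distance
  expect_gt(ctx$W[1, 2], ctx$W[1, 3])
  # d = 0 off-diagonal would give weight 1
  D2 <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3, 3)
  expect_equal(gaussian_similarity(D2)$W[1, 2], 1)
  expect_error(gaussian_similarity(matrix(0, 3, 3)), "degenerate")
})

test_that("all Laplacian kinds annihilate the constant vector", {
  set.seed(41)
  D <- as.matrix(dist(matrix(rnorm(12), 6, 2))) * 5
  ctx <- gaussian_similarity(D)
  for (kind in c("unnormalized", "random_walk")) {
    L <- build_laplacian(ctx, kind)
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-12)
  }
  Ls <- build_laplacian(ctx, "symmetric")
  expect_equal(max(abs(Ls %*% sqrt(ctx$degree))), 0, tolerance = 1e-10)
})

test_that("symmetric and random-walk Laplacians share eigenvalues via D^-1/2", {
  set.seed(42)
  D <- as.matrix(dist(matrix(rnorm(14), 7, 2))) * 4
  ctx <- gaussian_similarity(D)
  Ls <- build_laplacian(ctx, "symmetric")
  Lrw <- build_laplacian(ctx, "random_walk")
  es <- eigen(Ls, symmetric = TRUE)
  for (k in c(7, 6, 3)) {
    v <- es$vectors[, k] / sqrt(ctx$degree)
    expect_equal(as.numeric(Lrw %*% v), as.numeric(es$values[k] * v),
                 tolerance = 1e-8)
  }
})

test_that("the Fiedler vector separates two well-separated clusters", {
  # two tight 4-leaf clusters joined by one long central edge
  nwk <- paste0("(((A1:1,A2:1):1,(A3:1,A4:1):1):50,",
                "((B1:1,B2:1):1,(B3:1,B4:1):1):50);")
  D <- tree_metric(nwk)
  ctx <- gaussian_similarity(D)
  fr <- fiedler_vector(ctx, "random_walk")
  expect_gte(fr$eigenvalue, 0)
  expect_equal(sum(fr$vector^2), 1, tolerance = 1e-10)
  sgn <- sign(fr$vector)
  a_side <- sgn[startsWith(colnames(D), "A")]
  b_side <- sgn[startsWith(colnames(D), "B")]
  expect_true(all(a_side == a_side[1]))
  expect_true(all(b_side == b_side[1]))
  expect_true(a_side[1] != b_side[1])
  # two genomes: entries of opposite sign
  fr2 <- fiedler_vector(gaussian_similarity(matrix(c(0, 3, 3, 0), 2, 2)))
  expect_true(prod(sign(fr2$vector)) < 0)
})

test_that("a wide sign gap yields a non-overlapping decomposition", {
  nwk <- paste0("(((A1:1,A2:1):1,(A3:1,A4:1):1):50,",
                "((B1:1,B2:1):1,(B3:1,B4:1):1):50);")
  D <- tree_metric(nwk)
  dec <- decompose_disk(seq_len(8), D)
  expect_s3_class(dec, "disk_decomposition")
  expect_length(dec$overlap, 0)
  sides <- list(colnames(D)[dec$disk0], colnames(D)[dec$disk1])
  grp <- lapply(sides, function(s) unique(substr(s, 1, 1)))
  expect_setequal(unlist(grp), c("A", "B"))
  expect_length(grp[[1]], 1)
})

test_that("bridging genomes near the boundary land in the overlap", {
  # two clusters bridged by two mid genomes at intermediate distances
  nwk <- paste0("(((A1:1,A2:1):1,A3:1):8,(M1:1,M2:1):4,",
                "((B1:1,B2:1):1,B3:1):8);")
  D <- tree_metric(nwk)
  dec <- decompose_disk(seq_len(8), D,
                        dcm_params(theta1 = 2, theta2 = 0.4))
  ovn <- colnames(D)[dec$overlap]
  expect_true(all(c("M1", "M2") %in% ovn))
  # and both exclusive regions stay non-empty
  expect_gt(length(setdiff(dec$disk0, dec$overlap)), 0)
  expect_gt(length(setdiff(dec$disk1, dec$overlap)), 0)
})

test_that("big-overlap avoidance isolates a tight distant pair", {
  # two tight distant pairs and many central genomes (the long-edge trap)
  nwk <- paste0("((A0:1,A1:1):60,(C0:1,C1:1):60,",
                "(B0:2,(B1:2,(B2:2,(B3:2,(B4:2,B5:2):2):2):2):2):2);")
  D <- tree_metric(nwk)
  dec <- decompose_disk(seq_len(nrow(D)), D)
  expect_length(dec$overlap, 0)
  sides <- list(colnames(D)[dec$disk0], colnames(D)[dec$disk1])
  sizes <- vapply(sides, length, integer(1))
  small <- sides[[which.min(sizes)]]
  expect_true(identical(sort(small), c("A0", "A1")) ||
                identical(sort(small), c("C0", "C1")))
})

test_that("avoid_large_overlap leaves empty or non-triggering overlaps alone", {
  nwk <- paste0("(((A1:1,A2:1):1,(A3:1,A4:1):1):50,",
                "((B1:1,B2:1):1,(B3:1,B4:1):1):50);")
  D <- tree_metric(nwk)
  dec <- decompose_disk(seq_len(8), D)
  expect_identical(avoid_large_overlap(dec, D), dec)
})

test_that("disk trees terminate with leaf disks of at most three genomes", {
  set.seed(43)
  mt <- uniform_random_tree(17, 1, 12)
  mt <- evolve_genomes(mt, g = 60)
  D <- pairwise_matrix(mt$genomes)
  dt <- build_disk_tree(D)
  check <- function(node) {
    if (is.null(node$children)) {
      expect_lte(length(node$disk), 3L)
      expect_gte(length(node$disk), 1L)
    } else {
      d <- node$decomp
      expect_setequal(union(d$disk0, d$disk1), d$parent)
      expect_lt(length(d$disk0), length(d$parent))
      expect_lt(length(d$disk1), length(d$parent))
      expect_gt(length(setdiff(d$disk0, d$overlap)), 0)
      expect_gt(length(setdiff(d$disk1, d$overlap)), 0)
      check(node$children[[1]])
      check(node$children[[2]])
    }
  }
  check(dt)
})

test_that("decomposition is deterministic and respects the overlap cap", {
  set.seed(44)
  mt <- uniform_random_tree(12, 0, 10)
  mt <- evolve_genomes(mt, g = 60)
  D <- pairwise_matrix(mt$genomes)
  p <- dcm_params(max_overlap_fraction = 0.25)
  d1 <- decompose_disk(seq_len(12), D, p)
  d2 <- decompose_disk(seq_len(12), D, p)
  expect_identical(d1[c("disk0", "disk1", "overlap")],
                   d2[c("disk0", "disk1", "overlap")])
  expect_lte(length(d1$overlap), floor(0.25 * 12))
})
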