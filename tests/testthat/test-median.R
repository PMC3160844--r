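# Inversion medians against the exhaustive oracle, and iterated median
# scoring of fixed topologies.

test_that("median degenerate cases follow the metric bounds", {
  a <- gene_order(1:5, "a")
  m <- inversion_median(a, a, a)
  expect_equal(m$score, 0L)
  expect_identical(unclass(m$median)[1:5], 1:5)

  cc <- gene_order(c(1, -3, -2, 4, 5), "c")
  m2 <- inversion_median(a, a, cc)
  expect_equal(m2$score, inversion_distance(a, cc))
  expect_false(m2$heuristic)
})

test_that("median score equals the exhaustive oracle on random triples", {
  set.seed(31)
  for (rep in 1:50) {
    g <- sample(4:6, 1)
    a <- random_genome(g, sample(0:3, 1), "a")
    b <- random_genome(g, sample(0:3, 1), "b")
    cc <- random_genome(g, sample(0:3, 1), "c")
    m <- inversion_median(a, b, cc)
    recomputed <- inversion_distance(m$median, a) +
      inversion_distance(m$median, b) + inversion_distance(m$median, cc)
    expect_equal(recomputed, m$score)
    expect_equal(m$score, oracle_median_score(a, b, cc))
    expect_false(m$heuristic)
    # metric lower bound
    per <- inversion_distance(a, b) + inversion_distance(a, cc) +
      inversion_distance(b, cc)
    expect_gte(m$score, ceiling(per / 2))
  }
})

test_that("median score is symmetric in its arguments", {
  set.seed(32)
  a <- random_genome(6, 2, "a"); b <- random_genome(6, 2, "b")
  cc <- random_genome(6, 2, "c")
  s1 <- inversion_median(a, b, cc)$score
  expect_equal(inversion_median(b, cc, a)$score, s1)
  expect_equal(inversion_median(cc, a, b)$score, s1)
})

test_that("initialize_label returns the median of its three arguments", {
  a <- gene_order(c(2, 1, 3), "a")
  expect_identical(as.integer(initialize_label(a, a, a)),
                   as.integer(unclass(a)))
  b <- gene_order(1:3, "b")
  expect_identical(as.integer(initialize_label(a, b, b)),
                   as.integer(unclass(b)))
  expect_error(initialize_label(a, NULL, b), "sequencing error")
  set.seed(33)
  x <- random_genome(5, 2, "x"); y <- random_genome(5, 2, "y")
  z <- random_genome(5, 2, "z")
  lab <- initialize_label(x, y, z)
  sc <- inversion_distance(lab, x) + inversion_distance(lab, y) +
    inversion_distance(lab, z)
  expect_equal(sc, oracle_median_score(x, y, z))
})

test_that("3-leaf star scoring equals the median score", {
  set.seed(34)
  gen <- lapply(1:3, function(i) random_genome(6, 2, sprintf("G%d", i)))
  st <- reconstruct(genome_set(gen))
  expect_equal(st$score,
               inversion_median(gen[[1]], gen[[2]], gen[[3]])$score)
})

test_that("identical leaves give score zero and identical internal labels", {
  gen <- lapply(1:4, function(i) gene_order(c(2, -1, 3, 4), paste0("L", i)))
  st <- reconstruct(genome_set(gen))
  expect_equal(st$score, 0L)
  for (lab in st$tree$labels) {
    expect_identical(abs(lab), abs(c(2L, -1L, 3L, 4L)))
  }
})

test_that("score_topology never beats the refined ground-truth labeling from above", {
  set.seed(35)
  for (rep in 1:3) {
    mt <- uniform_random_tree(6, 1, 5)
    mt <- evolve_genomes(mt, g = 20)
    truth <- mt$tree
    true_score <- tree_score(truth)
    st <- score_topology(truth)
    expect_lte(st$score, true_score)
    expect_equal(st$score, tree_score(st$tree))  # score is self-consistent
  }
})

test_that("score_topology rejects non-binary or unlabeled trees", {
  star5 <- spectree:::lt_make(
    matrix(c(1L, 6L, 2L, 6L, 3L, 6L, 4L, 6L, 5L, 6L), ncol = 2, byrow = TRUE),
    c(lapply(1:5, function(i) seq_len(4)), list(seq_len(4))),
    c(paste0("L", 1:5), ""), c(rep(TRUE, 5), FALSE))
  expect_error(score_topology(star5), "binary")
})
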