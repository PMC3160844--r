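# Model-tree simulators and inversion evolution.

test_that("uniform-random trees have binary arithmetic and bounded lengths", {
  for (n in c(3, 5, 9, 20)) {
    mt <- uniform_random_tree(n, 0, 16, seed = n)
    tr <- mt$tree
    expect_equal(sum(tr$leaf), n)
    expect_equal(nrow(tr$edges), 2 * n - 3)
    deg <- spectree:::lt_degree(tr)
    expect_true(all(deg[tr$leaf] == 1))
    expect_true(all(deg[!tr$leaf] == 3))
    ninternal <- sum(!tr$leaf[tr$edges[, 1]] & !tr$leaf[tr$edges[, 2]])
    expect_equal(ninternal, n - 3)
    expect_true(all(tr$lengths >= 0 & tr$lengths <= 16))
  }
  expect_error(uniform_random_tree(2), "n >= 3")
})

test_that("sequential leaf addition samples the 15 five-leaf topologies uniformly", {
  set.seed(61)
  draws <- 3000
  tops <- character(draws)
  for (i in seq_len(draws)) {
    mt <- uniform_random_tree(5, 1, 1)
    tops[i] <- canonical_topology(mt$tree)
  }
  tab <- table(tops)
  expect_length(tab, 15L)
  chi <- suppressWarnings(chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
  # binomial 3-sigma band around 1/15
  p <- 1 / 15
  band <- 3 * sqrt(p * (1 - p) / draws)
  expect_true(all(abs(tab / draws - p) < band + 1e-9))
})

test_that("pure-birth trees have n tips and positive durations", {
  for (n in c(3, 8, 20)) {
    mt <- birth_death_tree(n, birth = 0.001, death = 0, seed = n)
    expect_equal(sum(mt$tree$leaf), n)
    expect_true(all(mt$tree$lengths >= 0))
    # every started lineage survives: tips + internals = 2n - 1 vertices
    expect_equal(length(mt$tree$labels), 2 * n - 1)
  }
  expect_error(birth_death_tree(10, death = 0.5), "pure-birth")
})

test_that("waiting times to n tips match the Yule closed form", {
  # starting from 2 lineages, E[T_n] = sum_{k=2}^{n-1} 1/(birth k)
  set.seed(62)
  n <- 6; birth <- 0.001
  reps <- 1000
  totals <- numeric(reps)
  for (i in seq_len(reps)) {
    k <- 2
    t_tot <- 0
    while (k < n) {
      t_tot <- t_tot + rexp(1, rate = birth * k)
      k <- k + 1
    }
    totals[i] <- t_tot
  }
  expected <- sum(1 / (birth * (2:(n - 1))))
  expect_equal(mean(totals), expected, tolerance = 0.1)
  # and the simulator's root-to-event depths grow accordingly: total tree
  # duration (max root-tip path) exceeds the last speciation time
  mt <- birth_death_tree(n, birth = birth, death = 0, seed = 63)
  expect_gt(spectree:::tree_diameter(mt$tree), 0)
})

test_that("skew_and_scale hits the target diameter with bounded multipliers", {
  set.seed(64)
  skews <- numeric(0)
  for (rep in 1:20) {
    mt <- birth_death_tree(10, birth = 0.001, death = 0)
    mt2 <- skew_and_scale(mt, diameter_factor = 1, g = 100)
    expect_true(all(mt2$tree$lengths >= 0))
    dia <- spectree:::tree_diameter(mt2$tree)
    # integer rounding over ~a dozen path edges
    expect_lt(abs(dia - 100), 10)
    skews <- c(skews, mt2$tree$lengths)
    mt3 <- skew_and_scale(mt, diameter_factor = 2, g = 100)
    expect_lt(abs(spectree:::tree_diameter(mt3$tree) - 200), 16)
  }
  # log2-uniform multipliers produce a right-skewed length distribution
  expect_gt(mean(skews), median(skews))
})

test_that("inversion evolution respects edge counts and the metric bound", {
  set.seed(65)
  mt <- uniform_random_tree(8, 0, 6)
  mt <- evolve_genomes(mt, g = 40)
  tr <- mt$tree
  expect_false(any(vapply(tr$labels, is.null, logical(1))))
  for (k in seq_len(nrow(tr$edges))) {
    a <- tr$labels[[tr$edges[k, 1]]]
    b <- tr$labels[[tr$edges[k, 2]]]
    d <- inversion_distance(gene_order(a, "x"), gene_order(b, "y"))
    expect_lte(d, tr$lengths[k])
    if (tr$lengths[k] == 0) expect_equal(d, 0L)
  }
  expect_equal(length(mt$genomes), 8L)
  expect_equal(mt$genomes$g, 40L)
})

test_that("simulation is deterministic under a fixed seed", {
  r1 <- spectree:::simulate_regime("uniform", 8, 50, 99)
  r1 <- evolve_genomes(r1, g = 50)
  r2 <- spectree:::simulate_regime("uniform", 8, 50, 99)
  r2 <- evolve_genomes(r2, g = 50)
  expect_identical(r1$genomes$genomes, r2$genomes$genomes)
  expect_identical(r1$tree$lengths, r2$tree$lengths)
  r3 <- spectree:::simulate_regime("uniform", 8, 50, 100)
  r3 <- evolve_genomes(r3, g = 50)
  expect_false(identical(r1$genomes$genomes, r3$genomes$genomes))
})

test_that("gamma-distributed inversion lengths are clamped to [1, g]", {
  set.seed(66)
  mt <- uniform_random_tree(4, 2, 4)
  mt <- evolve_genomes(mt, g = 30, length_dist = "gamma",
                       gamma_shape = 2, gamma_rate = 0.5)
  expect_false(any(vapply(mt$tree$labels, is.null, logical(1))))
  for (lab in mt$tree$labels) {
    expect_identical(sort(abs(lab)), seq_len(30L))
  }
})
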