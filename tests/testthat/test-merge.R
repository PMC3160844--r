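# Merging sub-topologies: candidate enumeration bounds, conflict
# detection, overlap expansion, and the end-to-end reconstruct pipeline.

lt_single <- spectree:::lt_single

make_star3 <- function(genomes, nms) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  m <- spectree:::median3(cache, genomes[[1]], genomes[[2]], genomes[[3]],
                          20000L)
  spectree:::lt_make(matrix(c(1L, 4L, 2L, 4L, 3L, 4L), ncol = 2,
                            byrow = TRUE),
                     c(genomes, list(m$median)), c(nms, ""),
                     c(TRUE, TRUE, TRUE, FALSE))
}

test_that("merging two single genomes yields the two-leaf tree", {
  t0 <- lt_single(1:4, "A")
  t1 <- lt_single(c(-2, -1, 3, 4), "B")
  st <- merge_nonoverlapping(t0, t1)
  expect_equal(attr(st, "candidates"), 1L)
  expect_setequal(leaf_names(st$tree), c("A", "B"))
  expect_equal(st$score, 1L)
})

test_that("candidate counts follow the incident-edge arithmetic", {
  set.seed(51)
  g <- 40
  anc <- seq_len(g)
  mut <- function(x, k) {
    for (t in seq_len(k)) {
      ij <- rand_ij(g); i <- ij[1]; j <- ij[2]
      x <- rev_apply_oracle(x, i, j)
    }
    x
  }
  # two 3-leaf stars, far apart: closest cross pair is internal x internal
  base0 <- anc
  base1 <- mut(anc, 14)
  g0 <- lapply(1:3, function(i) gene_order(mut(base0, 2), paste0("A", i)))
  g1 <- lapply(1:3, function(i) gene_order(mut(base1, 2), paste0("B", i)))
  t0 <- make_star3(lapply(g0, function(x) as.integer(unclass(x))),
                   sapply(g0, attr, "name"))
  t1 <- make_star3(lapply(g1, function(x) as.integer(unclass(x))),
                   sapply(g1, attr, "name"))
  st <- merge_nonoverlapping(t0, t1)
  cp <- attr(st, "closest_pairs")
  if (nrow(cp) == 1L && !t0$leaf[cp[1, 1]] && !t1$leaf[cp[1, 2]]) {
    expect_equal(attr(st, "candidates"), 9L)   # 3 x 3 incident edges
  }
  expect_lte(attr(st, "candidates"), 9L * nrow(cp))
  expect_setequal(leaf_names(st$tree), c(paste0("A", 1:3), paste0("B", 1:3)))

  # single genome x 3-leaf star: 1 x 3 candidates when the closest vertex
  # is the internal one
  solo <- lt_single(mut(base1, 1), "S")
  st2 <- merge_nonoverlapping(t1, solo)
  cp2 <- attr(st2, "closest_pairs")
  if (nrow(cp2) == 1L && !t1$leaf[cp2[1, 1]]) {
    expect_equal(attr(st2, "candidates"), 3L)
  }
  expect_lte(attr(st2, "candidates"), 3L * nrow(cp2))
})

test_that("swapping the merge arguments yields the same score", {
  set.seed(52)
  gen <- lapply(1:6, function(i) random_genome(20, 2, sprintf("G%d", i)))
  t0 <- make_star3(lapply(gen[1:3], function(x) as.integer(unclass(x))),
                   paste0("G", 1:3))
  t1 <- make_star3(lapply(gen[4:6], function(x) as.integer(unclass(x))),
                   paste0("G", 4:6))
  s_ab <- merge_nonoverlapping(t0, t1)$score
  s_ba <- merge_nonoverlapping(t1, t0)$score
  expect_equal(s_ab, s_ba)
})

test_that("conflicting overlap edges are detected by split incompatibility", {
  # identical restricted topologies: no conflicts
  set.seed(53)
  mt <- uniform_random_tree(8, 1, 6)
  mt <- evolve_genomes(mt, g = 30)
  tr <- score_topology(mt$tree)$tree
  ov <- leaf_names(tr)[1:4]
  conf <- conflicting_overlap_edges(tr, tr, ov)
  expect_length(conf$edges0, 0)
  expect_length(conf$edges1, 0)
  # overlap of three genomes: no internal edges in the restriction
  conf3 <- conflicting_overlap_edges(tr, tr, leaf_names(tr)[1:3])
  expect_length(conf3$edges0, 0)
  expect_error(conflicting_overlap_edges(tr, tr, character(0)), "overlap")

  # AB|CD against AC|BD: the two central edges conflict
  q1 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  q2 <- read_newick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  conf4 <- conflicting_overlap_edges(q1, q2, c("A", "B", "C", "D"))
  expect_equal(length(conf4$edges0), 1L)
  expect_equal(length(conf4$edges1), 1L)
  # the conflicting edge is internal in both quartets
  e0 <- conf4$edges0
  expect_false(q1$leaf[q1$edges[e0, 1]] || q1$leaf[q1$edges[e0, 2]])
})

test_that("overlap merge candidate counts follow the resolution arithmetic", {
  set.seed(54)
  g <- 30
  anc <- seq_len(g)
  mut <- function(x, k) {
    for (t in seq_len(k)) {
      ij <- rand_ij(g); i <- ij[1]; j <- ij[2]
      x <- rev_apply_oracle(x, i, j)
    }
    x
  }
  # conflict-free: two 4-leaf trees sharing a cherry (Z1, Z2); exclusive
  # pieces attach on distinct sides
  z1 <- mut(anc, 2); z2 <- mut(z1, 1)
  a1 <- mut(anc, 5); a2 <- mut(a1, 1)
  b1 <- mut(z2, 5); b2 <- mut(b1, 1)
  t0 <- reconstruct(genome_set(list(
    gene_order(z1, "Z1"), gene_order(z2, "Z2"),
    gene_order(a1, "A1"), gene_order(a2, "A2"))))$tree
  t1 <- reconstruct(genome_set(list(
    gene_order(z1, "Z1"), gene_order(z2, "Z2"),
    gene_order(b1, "B1"), gene_order(b2, "B2"))))$tree
  st <- merge_overlapping(t0, t1, c("Z1", "Z2"))
  expect_setequal(leaf_names(st$tree),
                  c("Z1", "Z2", "A1", "A2", "B1", "B2"))
  expect_equal(st$score, tree_score(st$tree))
})

test_that("multifurcation resolution counts are (2k-5)!! and multiply", {
  # degree-4 vertex: 3 resolutions
  r4 <- spectree:::resolutions_of_degree(4L)
  expect_length(r4, 3L)
  r5 <- spectree:::resolutions_of_degree(5L)
  expect_length(r5, 15L)
  # a tree with one degree-4 multifurcation enumerates 3 candidates
  star4 <- spectree:::lt_make(
    matrix(c(1L, 5L, 2L, 5L, 3L, 5L, 4L, 5L), ncol = 2, byrow = TRUE),
    vector("list", 5), c("A", "B", "C", "D", ""),
    c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cands <- spectree:::lt_enumerate_resolutions(star4)
  expect_length(cands, 3L)
  tops <- sapply(cands, canonical_topology)
  expect_length(unique(tops), 3L)
  # two independent degree-4 multifurcations: 3 x 3 = 9 candidates
  two4 <- spectree:::lt_make(
    matrix(c(1L, 7L, 2L, 7L, 3L, 7L, 7L, 8L, 4L, 8L, 5L, 8L, 6L, 8L),
           ncol = 2, byrow = TRUE),
    vector("list", 8), c(paste0("L", 1:6), "", ""),
    c(rep(TRUE, 6), FALSE, FALSE))
  cands2 <- spectree:::lt_enumerate_resolutions(two4)
  expect_length(cands2, 9L)
  # the cap truncates with a warning
  expect_warning(spectree:::lt_enumerate_resolutions(two4, 4L), "truncated")
})

test_that("reconstruct recovers a quartet with one long internal edge", {
  set.seed(55)
  for (rep in 1:5) {
    mt <- build_model("((A:2,B:2):10,(C:2,D:2):1);", g = 40,
                      seed = 100 + rep)
    st <- reconstruct(mt$genomes)
    expect_setequal(leaf_names(st$tree), c("A", "B", "C", "D"))
    splits <- spectree:::lt_internal_splits(st$tree)
    expect_equal(length(splits), 1L)
    expect_true(splits %in% c("C|D", "A|B"))  # AB|CD split, canonical form
    # exhaustive cross-check: the reported score is the 3-topology minimum
    expect_equal(st$score, exhaustive_mp_score(mt$genomes))
  }
})

test_that("reconstruct handles duplicates as zero-length cherries", {
  set.seed(56)
  gen <- lapply(1:5, function(i) random_genome(20, 3, sprintf("G%d", i)))
  gen[[6]] <- gene_order(as.integer(unclass(gen[[2]])), "G6dup")
  st <- reconstruct(genome_set(gen))
  expect_setequal(leaf_names(st$tree), sapply(gen, attr, "name"))
  # the duplicate sits at distance zero from its twin
  D <- matrix(0, 6, 6)
  splits <- spectree:::lt_internal_splits(st$tree)
  tr <- st$tree
  v2 <- which(tr$leaf & tr$vnames == "G2")
  v6 <- which(tr$leaf & tr$vnames == "G6dup")
  adj <- spectree:::lt_adj(tr)
  expect_equal(adj[[v2]], adj[[v6]])  # attached as a cherry
})

test_that("reconstruct score equals a from-scratch recomputation", {
  set.seed(57)
  mt <- uniform_random_tree(10, 0, 8)
  mt <- evolve_genomes(mt, g = 50)
  st <- reconstruct(mt$genomes)
  expect_equal(st$score, tree_score(st$tree))
  expect_setequal(leaf_names(st$tree), names(mt$genomes$genomes))
})
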