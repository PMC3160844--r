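# Topological accuracy (FP/FN), decomposition compatibility and the
# merge-replay recoverability probe.

test_that("internal bipartitions apply the 0.5 length threshold", {
  tr <- read_newick(text = "((A:1,B:1):2,(C:1,D:1):1,E:1);")
  expect_length(internal_bipartitions(tr), 2L)
  # an internal edge of length 0.4 disappears
  tr2 <- read_newick(text = "((A:1,B:1):0.4,(C:1,D:1):1,E:1);")
  s2 <- internal_bipartitions(tr2)
  expect_length(s2, 1L)
  expect_false("A|B" %in% s2)
  # all internal lengths zero: nothing remains
  tr3 <- read_newick(text = "((A:1,B:1):0,(C:1,D:1):0,E:1);")
  expect_length(internal_bipartitions(tr3), 0L)
  # fewer than four leaves: empty set
  expect_length(internal_bipartitions(read_newick(text = "(A:1,B:1,C:1);")),
                0L)
  # without lengths, a binary tree yields n - 3 bipartitions
  tr4 <- read_newick(text = "((A,B),(C,D),(E,(F,G)));")
  tr4$lengths <- NULL
  expect_length(internal_bipartitions(tr4), 7 - 3)
})

test_that("fp_fn counts internal-edge errors only", {
  t1 <- read_newick(text = "((A,B),(C,D),E);")
  t1$lengths <- NULL
  r <- fp_fn(t1, t1)
  expect_equal(c(r$fp, r$fn), c(0L, 0L))
  # star against a binary model: FP 0, FN = n - 3
  model <- read_newick(text = "((A,B),(C,D),(E,F));")
  model$lengths <- NULL
  star <- spectree:::lt_make(
    cbind(1:6, rep(7L, 6)), vector("list", 7),
    c("A", "B", "C", "D", "E", "F", ""), c(rep(TRUE, 6), FALSE))
  r2 <- fp_fn(star, model)
  expect_equal(c(r2$fp, r2$fn), c(0L, 3L))
  expect_equal(r2$n_internal_model, 3L)
  # swapped quartets: FP 1, FN 1
  q1 <- read_newick(text = "((A,B),(C,D));")
  q2 <- read_newick(text = "((A,C),(B,D));")
  q1$lengths <- NULL; q2$lengths <- NULL
  r3 <- fp_fn(q1, q2)
  expect_equal(c(r3$fp, r3$fn), c(1L, 1L))
  expect_error(fp_fn(q1, read_newick(text = "((A,B),(C,E));")),
               "same leaf names")
})

test_that("FP+FN matches the Robinson-Foulds distance from ape", {
  set.seed(71)
  for (rep in 1:10) {
    ph1 <- ape::rtree(8, br = NULL)
    ph2 <- ape::rtree(8, br = NULL)
    ph1 <- ape::unroot(ph1); ph2 <- ape::unroot(ph2)
    t1 <- spectree:::lt_from_phylo(ph1)
    t2 <- spectree:::lt_from_phylo(ph2)
    r <- fp_fn(t1, t2)
    rf <- ape::dist.topo(ph1, ph2)[1]
    expect_equal(r$fp + r$fn, as.integer(rf))
    expect_equal(r$fp, r$fn)  # two binary trees on the same leaves
  }
})

test_that("decomposition compatibility follows the model-tree edges", {
  mt <- build_model("(((A1:2,A2:2):3,(B1:2,B2:2):3):3,(C1:2,C2:2):3);",
                    g = 30, seed = 7)
  nms <- names(mt$genomes$genomes)
  idx <- function(x) match(x, nms)
  # exclusive regions on the two sides of the A-clade edge: compatible
  d1 <- spectree:::new_decomp(idx(nms), idx(c("A1", "A2")),
                              idx(c("B1", "B2", "C1", "C2")), integer(0))
  expect_equal(classify_decomposition(d1, mt, nms), "compatible")
  # a single-genome exclusive region is always compatible
  d2 <- spectree:::new_decomp(idx(nms), idx("A1"),
                              idx(setdiff(nms, "A1")), integer(0))
  expect_equal(classify_decomposition(d2, mt, nms), "compatible")
  # mixing clades across exclusive regions with no separating edge
  d3 <- spectree:::new_decomp(idx(nms), idx(c("A1", "B1")),
                              idx(c("A2", "B2", "C1", "C2")), integer(0))
  expect_equal(classify_decomposition(d3, mt, nms), "incompatible")
  expect_error(classify_decomposition(
    spectree:::new_decomp(1:2, 1L, 2L, integer(0)), mt, c("zz", "yy")),
    "absent")
})

test_that("the three-clade overlap configuration is incompatible yet recoverable", {
  mt <- three_clade_fixture()
  nms <- names(mt$genomes$genomes)
  idx <- function(x) match(x, nms)
  ex0 <- c("A0", "C1", "C2", "C3", "C4")
  ex1 <- c("A2", "A3", "B2", "B3", "B4")
  ov <- c("A1", "B0", "B1", "C0")
  dec <- spectree:::new_decomp(idx(nms), idx(c(ex0, ov)), idx(c(ex1, ov)),
                               idx(ov))
  expect_equal(classify_decomposition(dec, mt, nms), "incompatible")
  expect_equal(merge_replay(dec, mt, nms), "recoverable")
})

test_that("compatible decompositions are vacuously recoverable", {
  mt <- three_clade_fixture(11)
  nms <- names(mt$genomes$genomes)
  idx <- function(x) match(x, nms)
  dec <- spectree:::new_decomp(idx(nms), idx(paste0("A", 0:3)),
                               idx(setdiff(nms, paste0("A", 0:3))),
                               integer(0))
  expect_equal(classify_decomposition(dec, mt, nms), "compatible")
  expect_equal(merge_replay(dec, mt, nms), "recoverable")
})

test_that("splitting a strong cherry across exclusive regions is irrecoverable", {
  # (X1, X2) is a tight cherry isolated by long edges; separating X1 from
  # X2 with an empty overlap cannot be repaired by any merge
  mt <- build_model(paste0("((X1:1,X2:1):20,(Y1:2,Y2:2):8,",
                           "(Z1:2,Z2:2):8);"), g = 60, seed = 13)
  nms <- names(mt$genomes$genomes)
  idx <- function(x) match(x, nms)
  dec <- spectree:::new_decomp(idx(nms), idx(c("X1", "Y1", "Y2")),
                               idx(c("X2", "Z1", "Z2")), integer(0))
  expect_equal(classify_decomposition(dec, mt, nms), "incompatible")
  expect_equal(merge_replay(dec, mt, nms), "irrecoverable")
})
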