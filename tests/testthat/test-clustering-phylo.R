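test_that("p-distance basics, symmetry, and pairwise deletion", {
  expect_equal(p_distance(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "ACGT", b = "ACGA"))["a", "b"], 0.25)
  # N and gaps are deleted pairwise
  d <- p_distance(c(a = "ACGTNA", b = "ACTTCA"))
  expect_equal(d["a", "b"], 0.2)   # 5 comparable sites, 1 mismatch
  expect_error(p_distance(c(a = "ACGT", b = "ACG")), "aligned")
  m <- p_distance(c(x = "ACGTAC", y = "AGGTAC", z = "ACGTTT"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
})

test_that("p-distance of a mutated pair matches the substitution rate", {
  seq <- random_sequence(9999, seed = 1234)
  withr::with_seed(99, {
    mut <- cubtools:::mutate_sequence(seq, 0.1)
  })
  d <- p_distance(c(anc = seq, der = mut))["anc", "der"]
  expect_lt(abs(d - 0.1), 0.01)
})

test_that("NJ recovers a hand-built additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,C:3,D:4) -> additive distances
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), LETTERS[1:4])
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], d)
  # AB|CD is the single non-trivial split
  expect_equal(compare_trees(tr, ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")), 0)
})

test_that("NJ three-taxon closed form and tie-break determinism", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(cophenetic(tr)[c("x", "y", "z"), c("x", "y", "z")], d)
  # branch lengths from the three-point formulas: 0.5, 1.5, 2.5
  expect_equal(sort(tr$edge.length), c(0.5, 1.5, 2.5))

  eq <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(eq) <- 0
  t1 <- ape::write.tree(neighbor_joining(eq))
  t2 <- ape::write.tree(neighbor_joining(eq))
  expect_identical(t1, t2)
})

test_that("NJ reconstructs random additive matrices and agrees with ape", {
  for (i in 1:20) {
    n <- sample(5:8, 1)
    gen <- random_additive_matrix(n, seed = 300 + i)
    tr <- neighbor_joining(gen$d)
    expect_equal(compare_trees(tr, gen$tree), 0)
    labs <- rownames(gen$d)
    expect_equal(cophenetic(tr)[labs, labs], gen$d, tolerance = 1e-9)
    # independent oracle: ape's NJ gives the same topology
    expect_equal(compare_trees(tr, ape::nj(as.dist(gen$d))), 0)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("negative NJ branch lengths are clamped, distances preserved for the pair", {
  d <- matrix(c(0, 0.1, 5, 5.2,
                0.1, 0, 5.1, 4.8,
                5, 5.1, 0, 0.3,
                5.2, 4.8, 0.3, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("hierarchical clustering heights match hand values and the naive oracle", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(hierarchical_cluster(m)$height, 0)

  m <- rbind(p = c(0, 0), q = c(3, 4))
  expect_equal(hierarchical_cluster(m)$height, 5)

  withr::with_seed(77, m5 <- matrix(rnorm(5 * 8), 5, 8,
                                    dimnames = list(paste0("s", 1:5), NULL)))
  h <- hierarchical_cluster(m5, linkage = "complete")
  expect_equal(h$height, oracle_complete_linkage_heights(m5),
               tolerance = 1e-12)

  # row permutation changes labels only
  perm <- c(3, 1, 5, 2, 4)
  h2 <- hierarchical_cluster(m5[perm, ], linkage = "complete")
  expect_equal(sort(h2$height), sort(h$height))
  expect_equal(compare_trees(ape::as.phylo(h), ape::as.phylo(h2)), 0)

  expect_message(hierarchical_cluster(rbind(a = c(NA, 1), b = c(0, 0))),
                 "imputing")
  expect_error(hierarchical_cluster(m5[1, , drop = FALSE]), "at least 2")

  mt <- merge_table(h)
  expect_equal(nrow(mt), 4)
  expect_setequal(attr(mt, "leaf_order"), rownames(m5))
})

test_that("Robinson-Foulds distance matches the bipartition oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(compare_trees(t1, t1), 0)
  expect_equal(compare_trees(t1, t2), 2)
  expect_error(compare_trees(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "label")
  for (i in 1:10) {
    withr::with_seed(500 + i, {
      a <- ape::rtree(7)
      b <- ape::rtree(7)
    })
    expect_equal(compare_trees(a, b),
                 as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("PHYLIP square distance matrices round-trip", {
  gen <- random_additive_matrix(5, seed = 42)
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(gen$d, f)
  back <- read_phylip_dist(f)
  expect_equal(back, gen$d, tolerance = 1e-6)
  bad <- withr::local_tempfile(fileext = ".dist")
  writeLines("not phylip", bad)
  expect_error(read_phylip_dist(bad), "malformed")
})
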