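# Distance conversion, UPGMA and Robinson-Foulds split distance.

test_that("identities convert to distances with missing-pair handling", {
  d <- identity_to_distance(c("a", "a", "b"), c("b", "c", "c"),
                            c(100, 60, 80))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.4)
  expect_equal(d["b", "c"], 0.2)
  expect_equal(d, t(d))

  expect_error(identity_to_distance(c("a"), c("b"), 90,
                                    genomes = c("a", "b", "c")),
               class = "markerAAI_incomplete_matrix")
  d2 <- identity_to_distance(c("a"), c("b"), 90, genomes = c("a", "b", "c"),
                             on_missing = "drop")
  expect_setequal(rownames(d2), c("a", "b"))
})

test_that("UPGMA reproduces the hand-worked four-taxon agglomeration", {
  d <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 6,
                6, 6, 6, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- upgma(d)
  # topology (((A,B),C),D) with merge heights 1, 2, 3
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(coph, d)                       # heights = half cluster distance
  nd <- ape::node.depth.edgelength(tr)
  root_height <- max(nd)
  heights <- sort(root_height - nd[(5):(4 + tr$Nnode)])
  expect_equal(heights, c(1, 2, 3))
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(root_height - nd[ab], 1)
})

test_that("UPGMA matches average-linkage hclust on random matrices", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    m <- matrix(runif(n * n), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgma(d)
    nd <- ape::node.depth.edgelength(tr)
    expect_lt(max(abs(nd[1:n] - max(nd[1:n]))), 1e-9)   # ultrametric output
    coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    hc <- stats::cophenetic(stats::hclust(stats::as.dist(d), "average"))
    expect_equal(coph, as.matrix(hc)[rownames(d), colnames(d)],
                 tolerance = 1e-9)
  }
})

test_that("UPGMA recovers simulated ultrametric trees exactly", {
  for (s in 1:3) {
    tr0 <- sample_tree(10, 0.8, seed = s)
    d <- ape::cophenetic.phylo(tr0)
    tr <- upgma(d)
    expect_equal(split_distance(tr, tr0)$raw, 0L)
  }
})

test_that("all-equal distances collapse to a star under zero-branch collapsing", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  dimnames(d) <- list(letters[1:5], letters[1:5])
  star <- upgma(d, collapse = TRUE)
  expect_equal(star$Nnode, 1L)
  resolved <- sample_tree(5, 1, seed = 2, labels = letters[1:5])
  sd <- split_distance(star, resolved)
  expect_equal(sd$normalized, 1)   # maximal distance to any resolved tree
})

test_that("split distance agrees with a brute-force bipartition comparison", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(split_distance(t1, t1), list(raw = 0L, normalized = 0))
  sd <- split_distance(t1, t2)
  expect_equal(sd$raw, 2L)
  expect_equal(sd$normalized, 1)

  expect_error(split_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               class = "markerAAI_incompatible_trees")

  set.seed(10)
  trees <- lapply(1:8, function(i) sample_tree(7, 1, seed = i))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(split_distance(trees[[i]], trees[[j]])$raw,
                 markerAAI:::.bf_split_distance(trees[[i]], trees[[j]]))
    expect_equal(split_distance(trees[[i]], trees[[j]])$raw,
                 split_distance(trees[[j]], trees[[i]])$raw)
  }
})
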