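# Genome-evolution simulator: tree sampling, Jukes-Cantor substitution,
# dataset generation, determinism and generative-truth consistency.

test_that("sampled trees are ultrametric, binary and deterministic", {
  tr <- sample_tree(2, 0.1, seed = 3)
  nd <- ape::node.depth.edgelength(tr)
  expect_equal(unname(nd[1:2]), c(0.1, 0.1))

  expect_identical(ape::write.tree(sample_tree(5, 0.2, seed = 1)),
                   ape::write.tree(sample_tree(5, 0.2, seed = 1)))

  tr8 <- sample_tree(8, 0.5, seed = 2)
  expect_equal(tr8$Nnode, 7L)           # rooted binary: n - 1 internal nodes
  nd <- ape::node.depth.edgelength(tr8)
  expect_true(all(abs(nd[1:8] - 0.5) < 1e-9))

  expect_error(sample_tree(1, 0.1), class = "markerAAI_invalid_config")
})

test_that("sequence evolution matches the Jukes-Cantor identity expectation", {
  parent <- rand_nt(1, 10000)
  expect_identical(evolve_sequence(parent, 0, 4, seed = 1), parent)

  child <- evolve_sequence(parent, 0.5, 4, seed = 5)
  obs <- mean(strsplit(parent, "")[[1]] == strsplit(child, "")[[1]])
  exp_id <- jc_expected_identity(0.5, 4)   # 1/4 + 3/4 exp(-4/3 * d)
  se <- sqrt(exp_id * (1 - exp_id) / 10000)
  expect_lt(abs(obs - exp_id), 3 * se)

  pa <- rand_aa(1, 10000)
  ch <- evolve_sequence(pa, 0.5, 20, seed = 6)
  obs <- mean(strsplit(pa, "")[[1]] == strsplit(ch, "")[[1]])
  exp_id <- jc_expected_identity(0.5, 20)  # 1/20 + 19/20 exp(-20/19 * d)
  se <- sqrt(exp_id * (1 - exp_id) / 10000)
  expect_lt(abs(obs - exp_id), 3 * se)

  expect_error(evolve_sequence(parent, -0.1, 4),
               class = "markerAAI_invalid_config")
})

test_that("generated datasets honor presence, zero-rate genes and the layout", {
  cfg <- tiny_config(seed = 2)
  cfg$rate_multipliers["marker02"] <- 0
  dir <- tempfile("zr")
  gt <- generate_dataset(cfg, dir)
  co <- load_cohort(dir)

  # presence_prob = 1: every genome carries every gene
  for (g in co$genomes) {
    expect_setequal(names(g$markers), cfg$marker_labels)
    expect_setequal(names(g$proteome), cfg$bg_labels)
  }
  # a zero-rate gene is identical in all genomes
  m2 <- vapply(co$genomes, function(g) g$markers[["marker02"]][[1]], character(1))
  expect_length(unique(m2), 1)
  # 16S-like marker has the configured number of copies
  expect_length(co$genomes[[1]]$markers[["slow16s"]], cfg$n_16s_copies)
  unlink(dir, recursive = TRUE)
})

test_that("identical configs and seeds give byte-identical datasets", {
  d1 <- tempfile("detA"); d2 <- tempfile("detB")
  generate_dataset(tiny_config(seed = 9), d1)
  generate_dataset(tiny_config(seed = 9), d2)
  expect_identical(md5_tree(d1), md5_tree(d2))
  d3 <- tempfile("detC")
  generate_dataset(tiny_config(seed = 10), d3)
  expect_false(identical(md5_tree(d1), md5_tree(d3)))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("ground truth is self-consistent and round-trips through Newick", {
  dir <- tempfile("gt")
  cfg <- tiny_config(seed = 4)
  gt <- generate_dataset(cfg, dir)
  p <- gt$pairwise_path_lengths
  expect_equal(p, t(p))
  expect_true(all(diag(p) == 0))
  # cross-lineage paths reach twice the tree depth; within-lineage paths stay
  # inside twice the crown depth
  lin <- gt$lineages[rownames(p)]
  cross <- outer(lin, lin, "!=") & upper.tri(p)
  within <- outer(lin, lin, "==") & upper.tri(p)
  expect_true(all(p[cross] > 2 * cfg$crown_depth))
  expect_true(all(abs(p[cross] - 2 * cfg$tree_depth) < 1e-6 |
                    p[cross] < 2 * cfg$tree_depth))
  expect_true(all(p[within] <= 2 * cfg$crown_depth + 1e-9))

  reread <- read_newick(file.path(dir, "true_tree.nwk"))
  expect_equal(split_distance(reread, gt$true_tree)$raw, 0L)
  nd1 <- sort(ape::node.depth.edgelength(reread)[seq_along(reread$tip.label)])
  nd2 <- sort(ape::node.depth.edgelength(gt$true_tree)[seq_along(gt$true_tree$tip.label)])
  expect_lt(max(abs(nd1 - nd2)), 1e-9)
  # path lengths agree with the re-read tree's own branch-length sums
  p2 <- ape::cophenetic.phylo(reread)[rownames(p), colnames(p)]
  expect_lt(max(abs(p - p2)), 1e-8)
  unlink(dir, recursive = TRUE)
})

test_that("mean pairwise identity decreases with the rate multiplier", {
  genes <- sprintf("marker%02d", 1:5)
  mults <- setNames(c(0.1, 0.5, 1, 2, 3), genes)
  means <- matrix(NA_real_, 20, length(mults),
                  dimnames = list(NULL, genes))
  for (s in 1:20) {
    cfg <- sim_config(n_lineages = 1, genomes_per_lineage = 2, n_markers = 6,
                      n_background_genes = 1, marker_length_nt = 400,
                      len_16s_nt = 1000, protein_length_aa = 50,
                      tree_depth = 0.2, crown_depth = 0.2, n_16s_copies = 1,
                      copy_divergence = 0, presence_prob = 1, seed = s)
    cfg$rate_multipliers[genes] <- mults
    dir <- tempfile("mono")
    generate_dataset(cfg, dir)
    co <- load_cohort(dir)
    tab <- build_identity_table(co, genes = genes, scheme = nt_scheme)
    means[s, tab$gene_label] <- tab$identity
    unlink(dir, recursive = TRUE)
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) < 0))   # strictly decreasing in the multiplier
})
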