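# Marker extraction, identity table and conservation ranking.

test_that("16S-like copies are length-filtered with inclusive bounds", {
  genome <- structure(list(
    genome_id = "g", lineage = "L",
    markers = list(slow16s = c(`1` = strrep("A", 999),
                               `2` = strrep("A", 1000),
                               `3` = strrep("A", 1800),
                               `4` = strrep("A", 1801))),
    proteome = character(0)), class = "genome_record")
  kept <- extract_16s_like(genome)
  expect_equal(nchar(unname(kept)), c(1000, 1800))
  expect_false(attr(kept, "excluded"))

  genome$markers$slow16s <- c(strrep("A", 950), strrep("A", 1500),
                              strrep("A", 1900))
  expect_equal(nchar(unname(extract_16s_like(genome))), 1500)

  genome$markers$slow16s <- strrep("A", 500)
  empty <- extract_16s_like(genome)
  expect_length(empty, 0)
  expect_true(attr(empty, "excluded"))
})

test_that("identity table covers all pairs, uses the max-copy rule and leaves gaps missing", {
  x <- simulate_tiny(seed = 41)
  co <- x$cohort
  n <- length(co$genomes)
  tab <- build_identity_table(co, scheme = nt_scheme, len_16s = c(1000, 1800))
  expect_s3_class(tab, "marker_identity_table")
  pairs <- unique(paste(tab$genome_a, tab$genome_b))
  expect_length(pairs, n * (n - 1) / 2)
  expect_true(all(tab$genome_a < tab$genome_b))
  expect_true(all(tab$identity >= 0 & tab$identity <= 100))

  # two identical genomes: 100 everywhere
  co2 <- co
  co2$genomes <- co$genomes[1:2]
  co2$genomes[[2]] <- co2$genomes[[1]]
  co2$genomes[[2]]$genome_id <- "zz_copy"
  names(co2$genomes)[2] <- "zz_copy"
  tab2 <- build_identity_table(co2$genomes, scheme = nt_scheme)
  expect_true(all(tab2$identity == 100))

  # a gene absent from one genome yields no row, not zero
  co3 <- co
  co3$genomes[[1]]$markers[["marker01"]] <- NULL
  tab3 <- build_identity_table(co3$genomes, scheme = nt_scheme)
  g1 <- names(co3$genomes)[1]
  expect_false(any(tab3$gene_label == "marker01" &
                     (tab3$genome_a == g1 | tab3$genome_b == g1)))
  expect_true(any(tab3$gene_label == "marker02" &
                    (tab3$genome_a == g1 | tab3$genome_b == g1)))

  # the 16S rows equal the explicit pairmax over length-legitimate copies
  ga <- co$genomes[[1]]; gb <- co$genomes[[2]]
  expected <- percent_identity_pairmax(extract_16s_like(ga),
                                       extract_16s_like(gb), nt_scheme)
  row <- tab[tab$gene_label == "slow16s" &
               tab$genome_a == ga$genome_id & tab$genome_b == gb$genome_id, ]
  expect_equal(row$identity, expected)
  unlink(x$dir, recursive = TRUE)
})

test_that("per-pair ranks follow the most-similar-is-1 convention", {
  expect_equal(rank_markers_per_pair(c(g1 = 99, g2 = 95, g3 = 90)),
               c(g1 = 1, g2 = 2, g3 = 3))
  expect_equal(unname(rank_markers_per_pair(c(a = 97, b = 97, c = 97))),
               c(2, 2, 2))
  set.seed(5)
  x <- setNames(sample(50:100, 8), paste0("g", 1:8))
  r <- rank_markers_per_pair(x)
  expect_identical(names(sort(r)), names(sort(-x)))
  expect_error(rank_markers_per_pair(c(a = 1, b = NA)),
               class = "markerAAI_incomplete_pair")
})

test_that("rank rows conserve total rank mass under arbitrary ties", {
  set.seed(6)
  for (i in 1:50) {
    M <- sample(3:12, 1)
    vals <- sample(80:100, M, replace = TRUE)  # many ties
    r <- rank_markers_per_pair(setNames(vals, paste0("g", 1:M)))
    expect_equal(sum(r), M * (M + 1) / 2)
  }
})

test_that("ranking is invariant to gene order and excludes incomplete pairs", {
  x <- simulate_tiny(seed = 42, presence_prob = 0.8)
  tab <- build_identity_table(x$cohort, scheme = nt_scheme)
  genes <- sort(unique(tab$gene_label))
  rt <- rank_table(tab, genes)
  expect_true(all(abs(rowSums(rt) - length(genes) * (length(genes) + 1) / 2) < 1e-9))
  rt_perm <- rank_table(tab, rev(genes))
  expect_equal(rt[, genes], rt_perm[, genes])
  # with presence gaps, some pairs must have been dropped from ranking
  n <- length(x$cohort$genomes)
  expect_lt(nrow(rt), n * (n - 1) / 2)
  unlink(x$dir, recursive = TRUE)
})

test_that("lineage-average ranks recover the generative rate ordering", {
  wins <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_lineages = 1, genomes_per_lineage = 4, n_markers = 4,
                      n_background_genes = 1, marker_length_nt = 600,
                      len_16s_nt = 1000, protein_length_aa = 50,
                      tree_depth = 0.25, crown_depth = 0.25, n_16s_copies = 1,
                      copy_divergence = 0, presence_prob = 1, seed = 100 + s)
    mults <- c(marker01 = 0.1, marker02 = 1, marker03 = 3)
    cfg$rate_multipliers[names(mults)] <- mults
    dir <- tempfile("rank")
    gt <- generate_dataset(cfg, dir)
    co <- load_cohort(dir)
    tab <- build_identity_table(co, genes = names(mults), scheme = nt_scheme)
    lr <- average_rank_by_lineage(rank_table(tab, names(mults)),
                                  gt$lineages)
    rho <- spearman(mults[lr$gene_label], lr$mean_rank)$rho
    if (rho == 1) wins <- wins + 1
    unlink(dir, recursive = TRUE)
  }
  expect_gt(wins, 10)   # perfect recovery in the majority of seeds
})

test_that("single-pair averages and missing lineages behave as documented", {
  ranks <- matrix(c(1, 2, 3), 1, 3,
                  dimnames = list("a|b", c("g1", "g2", "g3")))
  lin <- c(a = "L1", b = "L1")
  out <- average_rank_by_lineage(ranks, lin)
  expect_equal(out$mean_rank, c(1, 2, 3))
  expect_equal(out$n_pairs, rep(1L, 3))

  ranks2 <- rbind(ranks, `a|b` = c(1, 2, 3))
  rownames(ranks2) <- c("a|b", "a|b")
  out2 <- average_rank_by_lineage(ranks2, lin)
  expect_equal(out2$mean_rank, c(1, 2, 3))

  expect_error(average_rank_by_lineage(ranks, c(a = "L1", b = "L2")),
               class = "markerAAI_insufficient_data")
})
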