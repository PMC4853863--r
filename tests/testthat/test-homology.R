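# Reciprocal-best-hit homology, AAI and the marker filters.

test_that("best hits and RBH on identical proteomes are the identity map", {
  set.seed(31)
  prot <- setNames(rand_aa(6, 80), paste0("p", 1:6))
  bh <- best_hits(prot, prot, aa_scheme)
  expect_identical(bh, setNames(names(prot), names(prot)))

  rbh <- reciprocal_best_hits(prot, prot, aa_scheme)
  expect_equal(nrow(rbh), 6)
  expect_identical(rbh$protein_id_a, rbh$protein_id_b)
  expect_true(all(rbh$identity == 100))

  aai <- aai_between(prot, prot, aa_scheme, min_homologs = 3)
  expect_equal(aai$aai, 100)
  expect_equal(aai$n_homologs, 6)
  expect_false(aai$discarded)
})

test_that("best hits equal the exhaustive all-vs-all argmax on toy proteomes", {
  set.seed(32)
  for (rep in 1:5) {
    qa <- setNames(rand_aa(3, 50), paste0("a", 1:3))
    qb <- setNames(rand_aa(3, 50), paste0("b", 1:3))
    # perturbed copies guarantee positive-scoring homologs
    qb[1] <- paste0(substr(qa[1], 1, 40), substr(qb[1], 41, 50))
    bh <- best_hits(qa, qb, aa_scheme, prefilter = FALSE)
    manual <- sapply(names(qa), function(q) {
      sc <- vapply(names(qb), function(s)
        local_align(qa[[q]], qb[[s]], aa_scheme)$score, numeric(1))
      if (max(sc) <= 0) NA_character_ else names(qb)[which.max(sc)]
    })
    manual <- manual[!is.na(manual)]
    expect_identical(bh, manual)
  }
})

test_that("non-reciprocal best hits are excluded and order does not matter", {
  base <- rand_aa(1, 60)
  a2 <- base
  a1 <- paste0(substr(base, 1, 40), rand_aa(1, 20))  # half-related to base
  pa <- c(a1 = a1, a2 = a2)
  pb <- c(b1 = base)
  rbh <- reciprocal_best_hits(pa, pb, aa_scheme, prefilter = FALSE)
  # b1's best hit is a2 (identical), so (a1, b1) must be excluded
  expect_equal(nrow(rbh), 1)
  expect_identical(rbh$protein_id_a, "a2")

  rbh_shuffled <- reciprocal_best_hits(pa[c(2, 1)], pb, aa_scheme,
                                       prefilter = FALSE)
  expect_identical(rbh, rbh_shuffled)
})

test_that("k-mer prefiltered search equals the exhaustive search on small sets", {
  set.seed(33)
  x <- simulate_tiny(seed = 33)
  pa <- x$cohort$genomes[[1]]$proteome[1:10]
  pb <- x$cohort$genomes[[5]]$proteome[1:10]
  r1 <- reciprocal_best_hits(pa, pb, aa_scheme, prefilter = TRUE, k = 3,
                             top_n = 10)
  r2 <- reciprocal_best_hits(pa, pb, aa_scheme, prefilter = FALSE)
  expect_identical(r1, r2)
  unlink(x$dir, recursive = TRUE)
})

test_that("homolog filters apply the canonical coverage and identity cutoffs", {
  pairs <- data.frame(
    protein_id_a = paste0("a", 1:4), protein_id_b = paste0("b", 1:4),
    identity = c(50, 50, 30.0, 30.1),
    coverage_shorter = c(0.69, 0.70, 0.95, 0.70),
    score = 100)
  kept <- filter_homologs(pairs)
  expect_identical(kept$protein_id_a, c("a2", "a4"))
})

test_that("AAI is the unweighted homolog mean, gated by the homolog count", {
  mk <- function(n) data.frame(identity = rep(c(50, 60, 70), length.out = n))
  expect_equal(compute_aai(mk(3), min_homologs = 3)$aai, 60)
  r199 <- compute_aai(mk(199), min_homologs = 200)
  expect_true(r199$discarded)
  expect_true(is.na(r199$aai))
  r200 <- compute_aai(mk(200), min_homologs = 200)
  expect_false(r200$discarded)
})

test_that("AAI is symmetric and decreases with genealogical distance", {
  x <- simulate_tiny(seed = 35, genomes_per_lineage = 3)
  gs <- x$cohort$genomes
  r_ab <- aai_between(gs[[1]]$proteome, gs[[2]]$proteome, aa_scheme,
                      min_homologs = 5)
  r_ba <- aai_between(gs[[2]]$proteome, gs[[1]]$proteome, aa_scheme,
                      min_homologs = 5)
  expect_equal(r_ab$aai, r_ba$aai)
  expect_equal(r_ab$n_homologs, r_ba$n_homologs)

  # within-lineage pair is closer than a cross-lineage pair
  other <- which(x$gt$lineages[names(gs)] != gs[[1]]$lineage)[1]
  r_far <- aai_between(gs[[1]]$proteome, gs[[other]]$proteome, aa_scheme,
                       min_homologs = 5)
  expect_gt(r_ab$aai, r_far$aai)
  unlink(x$dir, recursive = TRUE)
})

test_that("markers are recognized by RBH against a reference genome", {
  x <- simulate_tiny(seed = 36)
  gs <- x$cohort$genomes
  ref <- gs[[1]]$proteome[1:8]           # treat 8 reference proteins as markers
  self <- find_markers_by_rbh(gs[[1]]$proteome, ref, aa_scheme)
  expect_identical(self, setNames(names(ref), names(ref)))

  target <- gs[[4]]$proteome
  deleted <- names(target)[2]
  found <- find_markers_by_rbh(target[names(target) != deleted], ref, aa_scheme)
  if (deleted %in% names(ref)) expect_false(deleted %in% names(found))
  expect_true(all(setdiff(names(ref), deleted) %in% names(found)))
  unlink(x$dir, recursive = TRUE)
})

test_that("the presence filter is strictly greater-than", {
  presence <- c(g1 = 0.90, g2 = 0.91, g3 = 1.0, g4 = 0.50)
  expect_identical(marker_presence_filter(presence, 0.90), c("g2", "g3"))
  expect_error(marker_presence_filter(c(g = 1.2)),
               class = "markerAAI_invalid_input")
})

test_that("RBH marker detection tracks the simulated presence probability", {
  p_keep <- 0.85
  x <- simulate_tiny(seed = 37, presence_prob = p_keep,
                     n_background_genes = 40)
  gs <- x$cohort$genomes
  # reference: a genome completed with every gene from the cohort
  all_bg <- sprintf("bg%03d", 1:40)
  pool <- do.call(c, unname(lapply(gs, function(g) g$proteome)))
  ref <- pool[!duplicated(names(pool))][all_bg]
  hits <- 0; trials <- 0
  for (g in gs[2:7]) {
    found <- find_markers_by_rbh(g$proteome, ref, aa_scheme, top_n = 10)
    hits <- hits + length(found)
    trials <- trials + length(all_bg)
  }
  se <- sqrt(p_keep * (1 - p_keep) / trials)
  expect_lt(abs(hits / trials - p_keep), 3 * se)
  unlink(x$dir, recursive = TRUE)
})
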