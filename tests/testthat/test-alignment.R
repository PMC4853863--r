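# Pairwise alignment kernels: worked examples, oracle and cross-package
# checks, and algebraic properties.

test_that("global alignment reproduces worked nucleotide examples", {
  r <- global_align("ACGT", "ACGT", nt_scheme)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$aligned_a, "ACGT")
  expect_equal(r$aligned_b, "ACGT")
  expect_equal(r$coverage_shorter, 1)

  r <- global_align("ACGT", "ACGA", nt_scheme)
  expect_equal(r$percent_identity, 75)   # 3 identical columns of 4
  expect_equal(r$score, 3 * 5 - 4)

  # score agrees with the exhaustive enumeration oracle
  r2 <- global_align("AAAA", "AA", nt_scheme)
  expect_equal(r2$score, markerAAI:::.bf_global_score("AAAA", "AA", nt_scheme))
})

test_that("local alignment finds embedded matches and empty alignments", {
  p <- rand_aa(1, 30)
  r <- local_align(p, p, aa_scheme)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$coverage_shorter, 1)

  r <- local_align("MMMPQRWWW", "PQR", aa_scheme)
  expect_equal(r$aligned_a, "PQR")
  expect_equal(r$aligned_b, "PQR")
  expect_equal(r$percent_identity, 100)
  expect_equal(r$coverage_shorter, 1)

  # no positive-scoring residue pair: empty alignment with score 0
  r <- local_align("GGGG", "PPPP", aa_scheme)
  expect_equal(r$score, 0)
  expect_equal(r$percent_identity, 0)
  expect_equal(r$coverage_shorter, 0)
  expect_equal(r$aligned_a, "")
})

test_that("alignment scores match Biostrings pairwiseAlignment", {
  set.seed(42)
  sub_nt <- nt_scheme$smat[1:4, 1:4]
  for (i in 1:15) {
    a <- rand_nt(1, sample(10:40, 1))
    b <- rand_nt(1, sample(10:40, 1))
    bs_g <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = sub_nt,
      gapOpening = nt_scheme$gap_open, gapExtension = nt_scheme$gap_extend)
    expect_equal(global_align(a, b, nt_scheme)$score, Biostrings::score(bs_g))
    bs_l <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = sub_nt,
      gapOpening = nt_scheme$gap_open, gapExtension = nt_scheme$gap_extend)
    expect_equal(local_align(a, b, nt_scheme)$score, Biostrings::score(bs_l))
  }
  for (i in 1:10) {
    a <- rand_aa(1, sample(10:30, 1))
    b <- rand_aa(1, sample(10:30, 1))
    bs <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = aa_scheme$gap_open, gapExtension = aa_scheme$gap_extend)
    expect_equal(global_align(a, b, aa_scheme)$score, Biostrings::score(bs))
  }
})

test_that("percent identity is symmetric and suffix extension never lowers the score", {
  set.seed(7)
  for (i in 1:25) {
    a <- rand_nt(1, sample(5:25, 1))
    b <- rand_nt(1, sample(5:25, 1))
    expect_equal(global_align(a, b, nt_scheme)$percent_identity,
                 global_align(b, a, nt_scheme)$percent_identity)
    expect_equal(local_align(a, b, nt_scheme)$percent_identity,
                 local_align(b, a, nt_scheme)$percent_identity)
    s <- rand_nt(1, 6)
    expect_gte(global_align(paste0(a, s), paste0(b, s), nt_scheme)$score,
               global_align(a, b, nt_scheme)$score)
  }
})

test_that("maximal identity over gene copies picks the best copy pair", {
  x <- rand_nt(1, 100)
  expect_equal(percent_identity_pairmax(x, x, nt_scheme), 100)

  set.seed(11)
  y97 <- mutate_at(x, 3)   # 97 % identical to x
  y99 <- mutate_at(x, 1)   # 99 % identical to x
  expect_equal(percent_identity_pairmax(x, c(y97, y99), nt_scheme), 99)

  # 2x2 copies equal the explicit maximum over the four global alignments
  ca <- rand_nt(2, 40); cb <- rand_nt(2, 40)
  explicit <- max(outer(seq_along(ca), seq_along(cb), Vectorize(function(i, j)
    global_align(ca[i], cb[j], nt_scheme)$percent_identity)))
  expect_equal(percent_identity_pairmax(ca, cb, nt_scheme), explicit)

  expect_error(percent_identity_pairmax(character(0), x, nt_scheme),
               class = "markerAAI_missing_gene")
})

test_that("invalid alignment inputs are rejected", {
  expect_error(global_align("", "ACGT", nt_scheme),
               class = "markerAAI_invalid_input")
  expect_error(global_align("ACGU", "ACGT", nt_scheme), "alphabet")
  expect_error(scoring_scheme("nucleotide", gap_open = 1, gap_extend = 2),
               class = "markerAAI_invalid_config")
})
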