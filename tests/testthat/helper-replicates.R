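# Memoised desk-scale replicate runs shared by the acceptance-level tests.
# Each replicate simulates the default cohort with seed s, runs the full
# pipeline, and keeps only the small summary quantities the tests assert on.

.replicate_cache <- new.env(parent = emptyenv())

run_desk_replicate <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  dir <- tempfile(sprintf("desk%02d_", seed))
  out <- tempfile(sprintf("deskout%02d_", seed))
  gt <- generate_dataset(sim_config(seed = seed), dir)
  cohort <- load_cohort(dir)
  res <- suppressWarnings(
    run_all(cohort, desk_pipeline_config(seed = seed), out, quiet = TRUE))

  cc <- res$correlations
  close <- cc[cc$side == "close" & !is.na(cc$rho), , drop = FALSE]
  far <- cc[cc$side == "far" & !is.na(cc$rho), , drop = FALSE]
  close_ord <- close$gene_label[order(-close$rho)]
  far_ord <- far$gene_label[order(-far$rho)]
  rs <- res$rank_split

  # AAI vs genealogical distance (analyzable pairs only)
  aai_ok <- res$aai[!res$aai$discarded, , drop = FALSE]
  paths <- gt$pairwise_path_lengths[cbind(aai_ok$genome_a, aai_ok$genome_b)]
  aai_path_rho <- spearman(aai_ok$aai, paths)$rho
  terc <- cut(paths, quantile(paths, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  aai_by_path_bin <- tapply(aai_ok$aai, terc, mean)

  # per-gene mean identity for a fixed genome pair (rate monotonicity checks)
  pair_sel <- res$identity$genome_a == "L1_g01" & res$identity$genome_b == "L1_g02"
  pair_ident <- setNames(res$identity$identity[pair_sel],
                         res$identity$gene_label[pair_sel])

  val <- list(
    seed = seed,
    n_markers = length(unique(cc$gene_label)),
    n_close_defined = nrow(close),
    close_pos_16s = match("slow16s", close_ord),
    n_markers_beating_16s_close = if ("slow16s" %in% close$gene_label)
      sum(close$rho > close$rho[close$gene_label == "slow16s"])
    else sum(close$gene_label != "slow16s"),  # a flat 16S is beaten by all
    far_pos_16s = match("slow16s", far_ord),
    n_far_defined = nrow(far),
    rank_split_rho = rs$rho[rs$lineage == "gene_avg"],
    rank_split_p = rs$p[rs$lineage == "gene_avg"],
    binned_ci = res$binned_ci,
    aai_path_rho = aai_path_rho,
    aai_by_path_bin = aai_by_path_bin,
    pair_identity = pair_ident,
    n_discarded = sum(res$aai$discarded),
    n_pairs_pass_16s = sum(res$pairs_16s$pass))
  unlink(c(dir, out), recursive = TRUE)
  .replicate_cache[[key]] <- val
  val
}

desk_replicates <- function(seeds = 1:20) {
  lapply(seeds, run_desk_replicate)
}
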