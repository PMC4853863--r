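# End-to-end pipeline: cohort -> marker identities -> 16S prefilter -> AAI ->
# binned CIs -> threshold-split correlations -> per-lineage trees, ranks and
# rank-vs-split-distance correlations.

#' Pipeline configuration
#'
#' Thresholds follow the conventional AAI workflow: pairs enter the AAI
#' computation only when their maximal 16S-like identity is at least
#' `min_16s_identity` (default 80); homologs must cover >= 70 % of the
#' shorter protein with identity > 30 %; a pair's AAI is reported only with
#' at least `min_homologs` homologs (default 200); correlation analyses are
#' split at `aai_split_threshold` (default 95); binned confidence intervals
#' use 2 % bins, 20 samplings of 100 genome-disjoint pairs.
#'
#' @param seed integer seed for all stochastic stages (resampling).
#' @param nucleotide_scheme,protein_scheme scoring schemes.
#' @param min_16s_identity 16S prefilter for AAI, percent (inclusive).
#' @param min_homologs minimum homolog count for a reported AAI.
#' @param aai_split_threshold AAI split point for correlations, percent.
#' @param ci_bin_width,ci_n_samplings,ci_sample_size binned-CI parameters.
#' @param presence_threshold strict presence fraction for the marker set.
#' @param gene_16s label of the 16S-like gene.
#' @param len_16s inclusive 16S length window, bp.
#' @param prefilter,kmer_k,kmer_top_n reciprocal-best-hit search parameters.
#' @param min_tree_tips smallest leaf set for which per-marker trees are
#'   built and compared.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            nucleotide_scheme = scoring_scheme("nucleotide"),
                            protein_scheme = scoring_scheme("protein"),
                            min_16s_identity = 80,
                            min_homologs = 200,
                            aai_split_threshold = 95,
                            ci_bin_width = 2, ci_n_samplings = 20,
                            ci_sample_size = 100,
                            presence_threshold = 0.90,
                            gene_16s = "slow16s",
                            len_16s = c(1000, 1800),
                            prefilter = TRUE, kmer_k = 4, kmer_top_n = 20,
                            min_tree_tips = 4) {
  .chk(min_16s_identity >= 0 && min_16s_identity <= 100,
       "min_16s_identity must be in [0,100]", "invalid_config")
  .chk(min_homologs >= 1, "min_homologs must be >= 1", "invalid_config")
  .chk(aai_split_threshold > 0 && aai_split_threshold < 100,
       "aai_split_threshold must be in (0,100)", "invalid_config")
  .chk(presence_threshold >= 0 && presence_threshold < 1,
       "presence_threshold must be in [0,1)", "invalid_config")
  structure(
    list(seed = as.integer(seed),
         nucleotide_scheme = .as_scheme(nucleotide_scheme),
         protein_scheme = .as_scheme(protein_scheme),
         min_16s_identity = min_16s_identity,
         min_homologs = min_homologs,
         aai_split_threshold = aai_split_threshold,
         ci_bin_width = ci_bin_width, ci_n_samplings = ci_n_samplings,
         ci_sample_size = ci_sample_size,
         presence_threshold = presence_threshold,
         gene_16s = gene_16s, len_16s = len_16s,
         prefilter = prefilter, kmer_k = kmer_k, kmer_top_n = kmer_top_n,
         min_tree_tips = min_tree_tips),
    class = "pipeline_config")
}

#' Desk-scale pipeline configuration
#'
#' The companion of the default [sim_config()] cohort: identical thresholds
#' to [pipeline_config()] except that `min_homologs` is 80 (two thirds of
#' the simulated 120-gene proteomes, the proportion a threshold of 200 out
#' of a few thousand genes represents for real genomes) and the RBH
#' prefilter uses 3-mers with 5 candidates per query — small proteins at
#' sub-50 % identity share too few 4-mers for reliable candidate recall,
#' and the simulated proteomes carry no large paralogous families.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [pipeline_config()].
#' @export
desk_pipeline_config <- function(seed = 1, ...) {
  args <- list(seed = seed, min_homologs = 80, kmer_k = 3, kmer_top_n = 5)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config> 16S prefilter >= %g%%; min homologs %d; ",
                     "AAI split %g%%; CI %g%% bins x %d samplings of %d; seed %d\n"),
              x$min_16s_identity, x$min_homologs, x$aai_split_threshold,
              x$ci_bin_width, x$ci_n_samplings, x$ci_sample_size, x$seed))
  invisible(x)
}

# stable hash of the configuration, for stage caching
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load cohort; marker identity table (16S length filter
#' and maximal-identity-over-copies rule included); 16S >= threshold pair
#' prefilter; reciprocal-best-hit AAI with coverage/identity/homolog-count
#' filters; binned genome-disjoint AAI confidence intervals; per-gene
#' identity-vs-AAI correlations split at the AAI threshold; and per lineage:
#' the AAI tree, per-marker trees, split distances to the AAI tree, the
#' conservation rank table, and the Spearman correlation between
#' lineage-average rank and normalized split distance (also pooled across
#' lineages).  Every stage writes a TSV into `out_dir` and is skipped on
#' re-run when its output exists and the configuration hash matches
#' (`force = TRUE` recomputes).
#'
#' @param input a cohort directory or a `cohort` object.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param force recompute even when cached stage outputs match.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list of class `pipeline_result` with all stage
#'   tables and the output paths.
#' @export
run_all <- function(input, config = pipeline_config(), out_dir,
                    force = FALSE, quiet = FALSE) {
  .chk(inherits(config, "pipeline_config"), "config must be a pipeline_config",
       "invalid_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  hash <- .config_hash(config)
  hash_file <- file.path(out_dir, "config_hash.txt")
  cached_ok <- !force && file.exists(hash_file) &&
    identical(readLines(hash_file, warn = FALSE)[1], hash)
  writeLines(hash, hash_file)
  .echo_config(config, file.path(out_dir, "config.yaml"))

  log <- list()
  note <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, records_in, compute) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(compute(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    secs <- proc.time()[["elapsed"]] - t0
    n_out <- if (is.data.frame(res) || is.matrix(res)) nrow(res) else length(res)
    log[[length(log) + 1]] <<- data.frame(
      stage = name, records_in = records_in, records_out = n_out,
      seconds = round(secs, 3), stringsAsFactors = FALSE)
    note("[%s] %d -> %d records (%.1fs)", name, records_in, n_out, secs)
    res
  }
  cached_or <- function(file, compute) {
    path <- file.path(out_dir, file)
    if (cached_ok && file.exists(path)) return(.read_tsv(path))
    res <- compute()
    .write_tsv(res, path)
    res
  }

  cohort <- if (inherits(input, "cohort")) input else
    stage("load", NA_integer_, function() load_cohort(input))
  if (inherits(cohort, "cohort") && !length(log))
    log[[1]] <- data.frame(stage = "load", records_in = NA_integer_,
                           records_out = length(cohort$genomes),
                           seconds = 0, stringsAsFactors = FALSE)
  genomes <- cohort$genomes
  lineages <- cohort$lineages
  n_pairs <- choose(length(genomes), 2)

  identity <- stage("marker_identity", n_pairs, function()
    cached_or("marker_identity.tsv", function()
      build_identity_table(cohort, scheme = config$nucleotide_scheme,
                           gene_16s = config$gene_16s,
                           len_16s = config$len_16s)))

  # 16S prefilter: a pair passes when its maximal 16S-like identity (over
  # length-legitimate copies) is at least the threshold; pairs without any
  # legitimate 16S copy in either genome cannot pass
  ids <- sort(names(genomes))
  all_pairs <- t(utils::combn(ids, 2))
  p16 <- stage("prefilter_16s", n_pairs, function()
    cached_or("pairs_16s.tsv", function() {
      x <- pair_16s_identity(identity, config$gene_16s)
      full <- merge(data.frame(genome_a = all_pairs[, 1],
                               genome_b = all_pairs[, 2],
                               stringsAsFactors = FALSE),
                    x, by = c("genome_a", "genome_b"), all.x = TRUE)
      full$pass <- !is.na(full$identity_16s) &
        full$identity_16s >= config$min_16s_identity
      full[order(full$genome_a, full$genome_b), ]
    }))
  stopifnot(nrow(p16) == n_pairs,
            sum(p16$pass) + sum(!p16$pass) == n_pairs)

  aai <- stage("aai", sum(p16$pass), function()
    cached_or("aai.tsv", function() {
      pass <- p16[p16$pass, , drop = FALSE]
      out <- vector("list", nrow(pass))
      for (r in seq_len(nrow(pass))) {
        ga <- pass$genome_a[r]; gb <- pass$genome_b[r]
        out[[r]] <- aai_between(
          genomes[[ga]]$proteome, genomes[[gb]]$proteome,
          scheme = config$protein_scheme, min_homologs = config$min_homologs,
          genome_a = ga, genome_b = gb, prefilter = config$prefilter,
          k = config$kmer_k, top_n = config$kmer_top_n)
      }
      do.call(rbind, out)
    }))
  stopifnot(sum(!aai$discarded) + sum(aai$discarded) == nrow(aai))

  aai_ok <- aai[!aai$discarded, , drop = FALSE]
  ci_df <- merge(p16[p16$pass, c("genome_a", "genome_b", "identity_16s")],
                 aai_ok[, c("genome_a", "genome_b", "aai")],
                 by = c("genome_a", "genome_b"))
  ci <- stage("binned_ci", nrow(ci_df), function()
    cached_or("binned_ci.tsv", function()
      binned_ci(ci_df, bin_width = config$ci_bin_width,
                n_samplings = config$ci_n_samplings,
                sample_size = config$ci_sample_size, seed = config$seed)))

  corr_df <- merge(identity, aai_ok[, c("genome_a", "genome_b", "aai")],
                   by = c("genome_a", "genome_b"))
  correlations <- stage("split_correlations", nrow(corr_df), function()
    cached_or("correlations.tsv", function()
      split_correlations(corr_df, threshold = config$aai_split_threshold)))

  # marker set: genes present in > presence_threshold of genomes
  all_genes <- sort(unique(cohort$annotations$gene_label))
  presence <- vapply(all_genes, function(g)
    mean(vapply(genomes, function(rec) g %in% names(rec$markers), logical(1))),
    numeric(1))
  markers_used <- marker_presence_filter(presence, config$presence_threshold)
  presence_df <- stage("marker_presence", length(all_genes), function()
    cached_or("presence.tsv", function()
      data.frame(gene_label = all_genes, presence = unname(presence),
                 retained = all_genes %in% markers_used,
                 stringsAsFactors = FALSE)))

  ranks <- stage("ranks", nrow(identity), function() {
    rt <- rank_table(identity, markers_used)
    .write_tsv(data.frame(pair = rownames(rt), rt, check.names = FALSE),
               file.path(out_dir, "ranks.tsv"))
    rt
  })
  lineage_ranks <- stage("lineage_ranks", nrow(ranks), function()
    cached_or("lineage_ranks.tsv", function()
      average_rank_by_lineage(ranks, lineages)))

  trees_splits <- stage("trees", nrow(aai_ok), function()
    cached_or("split_distances.tsv", function()
      .lineage_trees(identity, aai_ok, lineages, markers_used, config,
                     out_dir)))

  rank_split <- stage("rank_vs_split", nrow(trees_splits), function()
    cached_or("rank_split_correlation.tsv", function()
      .rank_split_correlation(lineage_ranks, trees_splits)))

  log_df <- do.call(rbind, log)
  .write_tsv(log_df, file.path(out_dir, "pipeline_log.tsv"))

  invisible(structure(
    list(out_dir = out_dir, config = config, identity = identity,
         pairs_16s = p16, aai = aai, binned_ci = ci,
         correlations = correlations, presence = presence_df,
         markers_used = markers_used, ranks = ranks,
         lineage_ranks = lineage_ranks, split_distances = trees_splits,
         rank_split = rank_split, log = log_df),
    class = "pipeline_result"))
}

# per-lineage AAI tree, per-marker trees, split distances
.lineage_trees <- function(identity, aai_ok, lineages, markers_used, config,
                           out_dir) {
  out <- list()
  for (lin in sort(unique(lineages))) {
    members <- sort(names(lineages)[lineages == lin])
    if (length(members) < config$min_tree_tips) next
    within <- aai_ok$genome_a %in% members & aai_ok$genome_b %in% members
    sub <- aai_ok[within, , drop = FALSE]
    d_aai <- tryCatch(
      identity_to_distance(sub$genome_a, sub$genome_b, sub$aai,
                           genomes = members, on_missing = "drop"),
      markerAAI_error = function(e) NULL)
    if (is.null(d_aai) || nrow(d_aai) < config$min_tree_tips) next
    aai_tree <- upgma(d_aai, collapse = TRUE)
    write_newick(aai_tree, file.path(out_dir, "trees",
                                     paste0(lin, "_AAI.nwk")))
    core <- rownames(d_aai)
    for (gene in markers_used) {
      gsub_ <- identity[identity$gene_label == gene &
                          identity$genome_a %in% core &
                          identity$genome_b %in% core, , drop = FALSE]
      d_g <- tryCatch(
        identity_to_distance(gsub_$genome_a, gsub_$genome_b, gsub_$identity,
                             genomes = core, on_missing = "drop"),
        markerAAI_error = function(e) NULL)
      if (is.null(d_g) || nrow(d_g) < config$min_tree_tips) next
      g_tree <- upgma(d_g, collapse = TRUE)
      write_newick(g_tree, file.path(out_dir, "trees",
                                     paste0(lin, "_", gene, ".nwk")))
      ref <- if (length(setdiff(core, rownames(d_g))))
        ape::keep.tip(aai_tree, rownames(d_g)) else aai_tree
      sd <- split_distance(g_tree, ref)
      out[[paste(lin, gene)]] <- data.frame(
        lineage = lin, gene_label = gene, n_tips = nrow(d_g),
        raw_rf = sd$raw, normalized_rf = sd$normalized,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(lineage = character(0), gene_label = character(0),
                      n_tips = integer(0), raw_rf = integer(0),
                      normalized_rf = numeric(0))
  rownames(res) <- NULL
  res
}

# Spearman between lineage-average conservation rank and normalized split
# distance: per lineage, pooled over lineage-gene points, and on per-gene
# averages across lineages ("gene_avg", the headline aggregate — averaging
# cancels lineage-level split-distance offsets such as reference-tree noise)
.rank_split_correlation <- function(lineage_ranks, trees_splits) {
  joined <- merge(lineage_ranks, trees_splits, by = c("lineage", "gene_label"))
  do_one <- function(sub, label) {
    res <- tryCatch(spearman(sub$mean_rank, sub$normalized_rf),
                    markerAAI_error = function(e) e)
    if (inherits(res, "correlation_result"))
      data.frame(lineage = label, rho = res$rho, p = res$p_value, n = res$n,
                 note = "", stringsAsFactors = FALSE)
    else
      data.frame(lineage = label, rho = NA_real_, p = NA_real_,
                 n = nrow(sub), note = conditionMessage(res),
                 stringsAsFactors = FALSE)
  }
  if (nrow(joined) == 0) {
    return(data.frame(lineage = c("gene_avg", "pooled"), rho = NA_real_,
                      p = NA_real_, n = 0L,
                      note = "insufficient-data: no lineage trees built",
                      stringsAsFactors = FALSE))
  }
  ag <- stats::aggregate(cbind(mean_rank, normalized_rf) ~ gene_label,
                         data = joined, FUN = mean)
  out <- list(do_one(ag, "gene_avg"), do_one(joined, "pooled"))
  for (lin in sort(unique(joined$lineage)))
    out[[length(out) + 1]] <- do_one(joined[joined$lineage == lin, ], lin)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.echo_config <- function(config, path) {
  flat <- list(
    seed = config$seed,
    min_16s_identity = config$min_16s_identity,
    min_homologs = config$min_homologs,
    aai_split_threshold = config$aai_split_threshold,
    ci_bin_width = config$ci_bin_width,
    ci_n_samplings = config$ci_n_samplings,
    ci_sample_size = config$ci_sample_size,
    presence_threshold = config$presence_threshold,
    gene_16s = config$gene_16s,
    len_16s = config$len_16s,
    prefilter = config$prefilter,
    kmer_k = config$kmer_k, kmer_top_n = config$kmer_top_n,
    nucleotide_gap_open = config$nucleotide_scheme$gap_open,
    nucleotide_gap_extend = config$nucleotide_scheme$gap_extend,
    protein_gap_open = config$protein_scheme$gap_open,
    protein_gap_extend = config$protein_scheme$gap_extend)
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(flat), path)
  } else {
    writeLines(paste0(names(flat), ": ",
                      vapply(flat, function(v) paste(v, collapse = ","),
                             character(1))), path)
  }
  invisible(path)
}

#' Summarise a finished pipeline run
#'
#' @param out_dir output directory of [run_all()].
#' @return the summary text, invisibly; it is also printed.
#' @export
report <- function(out_dir) {
  need <- c("pairs_16s.tsv", "aai.tsv", "correlations.tsv",
            "lineage_ranks.tsv", "rank_split_correlation.tsv")
  for (f in need)
    .chk(file.exists(file.path(out_dir, f)),
         paste("missing-stage: no", f, "in", out_dir), "missing_stage")
  p16 <- .read_tsv(file.path(out_dir, "pairs_16s.tsv"))
  aai <- .read_tsv(file.path(out_dir, "aai.tsv"))
  corr <- .read_tsv(file.path(out_dir, "correlations.tsv"))
  lr <- .read_tsv(file.path(out_dir, "lineage_ranks.tsv"))
  rs <- .read_tsv(file.path(out_dir, "rank_split_correlation.tsv"))
  genomes <- unique(c(p16$genome_a, p16$genome_b))
  lines <- c(
    sprintf("markerAAI pipeline summary for %s", out_dir),
    sprintf("genomes: %d; pairs: %d; passing 16S >= threshold: %d",
            length(genomes), nrow(p16), sum(p16$pass)),
    sprintf("AAI records: %d analyzable, %d discarded (min homolog filter)",
            sum(!aai$discarded), sum(aai$discarded)))
  close_ok <- corr[corr$side == "close" & !is.na(corr$rho), , drop = FALSE]
  if (nrow(close_ok)) {
    ord <- close_ok$gene_label[order(-close_ok$rho)]
    pos <- match("slow16s", ord)
    lines <- c(lines, sprintf(
      "close-side (AAI > threshold) correlation: best %s (rho %.3f); slow16s position %s of %d",
      ord[1], max(close_ok$rho), ifelse(is.na(pos), "n/a", pos), length(ord)))
  } else {
    lines <- c(lines, "close-side correlations: zero analyzable pairs, no correlations")
  }
  for (lin in unique(lr$lineage)) {
    row <- rs[rs$lineage == lin, , drop = FALSE]
    if (nrow(row) && !is.na(row$rho[1]))
      lines <- c(lines, sprintf(
        "lineage %s: rank vs split-distance rho %.3f (p %.2g, n %d)",
        lin, row$rho[1], row$p[1], row$n[1]))
    else
      lines <- c(lines, sprintf("lineage %s: rank vs split-distance n/a", lin))
  }
  pooled <- rs[rs$lineage == "pooled", , drop = FALSE]
  if (nrow(pooled) && !is.na(pooled$rho[1]))
    lines <- c(lines, sprintf("pooled rank vs split-distance rho %.3f (p %.2g, n %d)",
                              pooled$rho[1], pooled$p[1], pooled$n[1]))
  ga <- rs[rs$lineage == "gene_avg", , drop = FALSE]
  if (nrow(ga) && !is.na(ga$rho[1]))
    lines <- c(lines, sprintf(
      "gene-averaged (across lineages) rank vs split-distance rho %.3f (p %.2g, n %d)",
      ga$rho[1], ga$p[1], ga$n[1]))
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d pairs, %d AAI records (%d discarded), %d markers ranked\n",
              x$out_dir, nrow(x$pairs_16s), nrow(x$aai), sum(x$aai$discarded),
              length(x$markers_used)))
  invisible(x)
}
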