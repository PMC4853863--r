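# Marker identity table and conservation ranking.

#' Extract 16S-like gene copies of legitimate length
#'
#' Returns the annotated copies of the genome's 16S-like gene whose length
#' lies within `[min_len, max_len]` (inclusive).  A genome with no surviving
#' copy is excluded from 16S-based analyses; the result then has length zero
#' and carries `attr(, "excluded") = TRUE`.
#'
#' @param genome a `genome_record` (see [load_cohort()]).
#' @param min_len,max_len inclusive length bounds (defaults 1000 and 1800 bp).
#' @param gene_label annotation label of the 16S-like gene.
#' @return character vector of surviving copies.
#' @export
extract_16s_like <- function(genome, min_len = 1000, max_len = 1800,
                             gene_label = "slow16s") {
  .chk(min_len <= max_len, "min_len must be <= max_len", "invalid_config")
  copies <- genome$markers[[gene_label]]
  if (is.null(copies)) copies <- character(0)
  keep <- copies[nchar(copies) >= min_len & nchar(copies) <= max_len]
  structure(keep, excluded = length(keep) == 0)
}

#' Marker percent-identity table for all genome pairs
#'
#' For each unordered genome pair and each gene present in both genomes, the
#' global-alignment percent identity of the gene's nucleotide sequences.
#' For multi-copy genes the maximal identity over all copy pairs is taken
#' (the rule used for 16S rRNA, applied uniformly).  The 16S-like gene is
#' first restricted to copies of legitimate length via [extract_16s_like()].
#' Pairs lacking a gene in either genome have no row for that gene (missing,
#' not zero).
#'
#' @param cohort a `cohort` from [load_cohort()], or a named list of
#'   `genome_record`s.
#' @param genes gene labels to align (default: all annotated genes).
#' @param scheme nucleotide [scoring_scheme()].
#' @param gene_16s label of the 16S-like gene (its copies are
#'   length-filtered); set to `NA` to disable the filter.
#' @param len_16s inclusive length window for 16S-like copies.
#' @return long-format data frame of class `marker_identity_table`:
#'   `genome_a`, `genome_b` (canonical order, a < b), `gene_label`,
#'   `identity`.
#' @export
build_identity_table <- function(cohort, genes = NULL,
                                 scheme = scoring_scheme("nucleotide"),
                                 gene_16s = "slow16s",
                                 len_16s = c(1000, 1800)) {
  genomes <- if (inherits(cohort, "cohort")) cohort$genomes else cohort
  .chk(length(genomes) >= 2, "need at least 2 genomes", "invalid_input")
  scheme <- .as_scheme(scheme)
  ids <- sort(names(genomes))
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(genomes, function(g) names(g$markers)))))

  # apply the 16S length filter once per genome
  seqs <- lapply(genomes, function(g) {
    m <- g$markers
    if (!is.na(gene_16s) && gene_16s %in% names(m)) {
      kept <- extract_16s_like(g, len_16s[1], len_16s[2], gene_16s)
      if (length(kept) == 0) m[[gene_16s]] <- NULL else m[[gene_16s]] <- kept
    }
    m
  })

  # flatten all required copy-vs-copy alignments into one batch
  task_a <- character(0); task_b <- character(0)
  task_key <- character(0)
  rows <- list()
  for (ai in seq_len(length(ids) - 1)) {
    for (bi in seq.int(ai + 1, length(ids))) {
      ga <- ids[ai]; gb <- ids[bi]
      for (gene in genes) {
        ca <- seqs[[ga]][[gene]]; cb <- seqs[[gb]][[gene]]
        if (is.null(ca) || is.null(cb) || !length(ca) || !length(cb)) next
        combos <- expand.grid(x = seq_along(ca), y = seq_along(cb))
        task_a <- c(task_a, unname(ca[combos$x]))
        task_b <- c(task_b, unname(cb[combos$y]))
        key <- paste(ga, gb, gene, sep = "\r")
        task_key <- c(task_key, rep(key, nrow(combos)))
        rows[[key]] <- c(ga, gb, gene)
      }
    }
  }
  if (!length(task_a)) {
    out <- data.frame(genome_a = character(0), genome_b = character(0),
                      gene_label = character(0), identity = numeric(0))
    class(out) <- c("marker_identity_table", "data.frame")
    return(out)
  }
  res <- cpp_nw_batch(task_a, task_b, scheme$smat, scheme$alphabet,
                      scheme$gap_open, scheme$gap_extend)
  pid <- 100 * res[, "n_identical"] / res[, "n_columns"]
  best <- tapply(pid, task_key, max)
  meta <- do.call(rbind, rows[names(best)])
  out <- data.frame(genome_a = meta[, 1], genome_b = meta[, 2],
                    gene_label = meta[, 3], identity = unname(best),
                    stringsAsFactors = FALSE)
  out <- out[order(out$genome_a, out$genome_b, out$gene_label), ]
  rownames(out) <- NULL
  class(out) <- c("marker_identity_table", "data.frame")
  out
}

# wide matrix [pair x gene] from the long table; missing entries NA
.identity_wide <- function(table, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(table$gene_label))
  pair <- paste(table$genome_a, table$genome_b, sep = "|")
  upair <- sort(unique(pair))
  m <- matrix(NA_real_, length(upair), length(genes),
              dimnames = list(upair, genes))
  sel <- table$gene_label %in% genes
  m[cbind(match(pair[sel], upair), match(table$gene_label[sel], genes))] <-
    table$identity[sel]
  m
}

#' Conservation ranks of marker genes within one genome pair
#'
#' The most similar (most conserved) gene receives rank 1 and the least
#' similar rank M; ties receive fractional (mean) ranks, so every row sums
#' to M(M+1)/2.
#'
#' @param row named numeric vector of per-gene percent identities for one
#'   genome pair; must be complete (no missing genes).
#' @return named numeric vector of ranks.
#' @export
rank_markers_per_pair <- function(row) {
  .chk(length(row) >= 2, "need at least 2 genes to rank", "invalid_input")
  if (anyNA(row))
    .err("incomplete-pair: missing identities; pair is excluded from ranking",
         "incomplete_pair")
  rank(-row, ties.method = "average")
}

#' Per-pair rank table over complete pairs
#'
#' Applies [rank_markers_per_pair()] to every genome pair for which all `M`
#' genes have identities (pairs missing any gene are excluded, mirroring the
#' restriction of ranking to genomes harboring the complete marker set).
#'
#' @param table a `marker_identity_table`.
#' @param genes gene labels defining the complete set (default: all genes in
#'   the table).
#' @return matrix [pair x gene] of ranks, with rownames `"a|b"`.
#' @export
rank_table <- function(table, genes = NULL) {
  wide <- .identity_wide(table, genes)
  complete <- !apply(is.na(wide), 1, any)
  wide <- wide[complete, , drop = FALSE]
  t(apply(wide, 1, function(r) rank(-r, ties.method = "average")))
}

#' Lineage-average conservation ranks
#'
#' Unweighted mean of per-pair ranks over all within-lineage pairs.  Lower
#' average ranks (closer to 1) correspond to more conserved genes.
#'
#' @param ranks rank matrix from [rank_table()].
#' @param lineages named vector: genome id -> lineage.
#' @return data frame `lineage`, `gene_label`, `mean_rank`, `n_pairs`.
#' @export
average_rank_by_lineage <- function(ranks, lineages) {
  pairs <- strsplit(rownames(ranks), "|", fixed = TRUE)
  lin_a <- lineages[vapply(pairs, `[`, character(1), 1)]
  lin_b <- lineages[vapply(pairs, `[`, character(1), 2)]
  within <- !is.na(lin_a) & lin_a == lin_b
  out <- list()
  for (lin in sort(unique(lineages))) {
    sel <- within & lin_a == lin
    if (!any(sel))
      .err(paste("insufficient-data: lineage", lin,
                 "has no complete within-lineage pair"), "insufficient_data")
    mr <- colMeans(ranks[sel, , drop = FALSE])
    out[[lin]] <- data.frame(lineage = lin, gene_label = names(mr),
                             mean_rank = unname(mr), n_pairs = sum(sel),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Maximal 16S-like identity per genome pair
#'
#' Convenience accessor: the `gene_16s` rows of a `marker_identity_table`
#' (which already apply the maximal-identity-over-copies rule).
#'
#' @param table a `marker_identity_table`.
#' @param gene_16s 16S-like gene label.
#' @return data frame `genome_a`, `genome_b`, `identity_16s`.
#' @export
pair_16s_identity <- function(table, gene_16s = "slow16s") {
  sel <- table[table$gene_label == gene_16s, , drop = FALSE]
  data.frame(genome_a = sel$genome_a, genome_b = sel$genome_b,
             identity_16s = sel$identity, stringsAsFactors = FALSE)
}
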