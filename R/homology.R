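# Reciprocal-best-hit homology and average amino-acid identity (AAI).
#
# The search engine is exhaustive Smith-Waterman, optionally restricted by a
# shared-k-mer candidate prefilter (default k = 4, top 20 candidates per
# query by shared-k-mer count).  Best hits are ranked by local-alignment
# score, ties broken by lexicographically smallest partner id, so results
# are deterministic and independent of input ordering.

# sparse score table for candidate pairs; scores are symmetric so one
# computation serves both search directions
.hit_scores <- function(a, b, scheme, prefilter = TRUE, k = 4, top_n = 20) {
  .chk(length(a) >= 1 && length(b) >= 1 && !is.null(names(a)) && !is.null(names(b)),
       "proteomes must be nonempty named character vectors", "invalid_input")
  if (prefilter) {
    sh <- cpp_kmer_shared(unname(a), unname(b), as.integer(k), scheme$alphabet)
    if (nrow(sh) == 0) return(data.frame(i = integer(0), j = integer(0),
                                         score = numeric(0)))
    keep_top <- function(idx, other, shared) {
      # per idx value keep top_n by shared count, ties by smallest other index
      o <- order(idx, -shared, other)
      sel <- unlist(lapply(split(o, idx[o]), utils::head, top_n), use.names = FALSE)
      sel
    }
    sel_a <- keep_top(sh$i, sh$j, sh$shared)
    sel_b <- keep_top(sh$j, sh$i, sh$shared)
    sel <- sort(unique(c(sel_a, sel_b)))
    cand <- sh[sel, c("i", "j")]
  } else {
    cand <- expand.grid(i = seq_along(a), j = seq_along(b))
  }
  cand$score <- cpp_sw_score_batch(unname(a), unname(b), cand$i, cand$j,
                                   scheme$smat, scheme$alphabet,
                                   scheme$gap_open, scheme$gap_extend)
  cand[cand$score > 0, , drop = FALSE]
}

# best partner per query index from a sparse score table
.best_by <- function(scores, query_col, subject_col, subject_names) {
  if (nrow(scores) == 0) return(integer(0))
  q <- scores[[query_col]]
  s <- scores[[subject_col]]
  o <- order(q, -scores$score, subject_names[s])
  first <- o[!duplicated(q[o])]
  setNames(s[first], q[first])  # names: query index, value: subject index
}

#' Best local-alignment hits between two proteomes
#'
#' For each query protein, the subject protein with the highest
#' Smith-Waterman score.  Queries with no positive-scoring hit are absent
#' from the result.  Ties are broken by the lexicographically smallest
#' subject id.
#'
#' @param query,subject named character vectors of amino-acid sequences.
#' @param scheme a protein [scoring_scheme()].
#' @param prefilter use the shared-k-mer candidate prefilter (disable to
#'   force the exhaustive all-vs-all search).
#' @param k,top_n prefilter parameters: k-mer size and candidates kept per
#'   query.
#' @return named character vector: query id -> best subject id.
#' @export
best_hits <- function(query, subject, scheme = scoring_scheme("protein"),
                      prefilter = TRUE, k = 4, top_n = 20) {
  scheme <- .as_scheme(scheme)
  sc <- .hit_scores(query, subject, scheme, prefilter, k, top_n)
  bh <- .best_by(sc, "i", "j", names(subject))
  setNames(names(subject)[bh], names(query)[as.integer(names(bh))])
}

#' Reciprocal best hits with Smith-Waterman re-alignment
#'
#' Protein pairs (x, y) such that y is x's best hit and x is y's best hit.
#' Each pair carries the percent identity and the coverage of the shorter
#' sequence from a full Smith-Waterman re-alignment.
#'
#' @inheritParams best_hits
#' @param proteome_a,proteome_b named character vectors of amino-acid
#'   sequences.
#' @return data frame with columns `protein_id_a`, `protein_id_b`,
#'   `identity` (percent), `coverage_shorter` (0-1), `score`; rows ordered
#'   by `protein_id_a`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 scheme = scoring_scheme("protein"),
                                 prefilter = TRUE, k = 4, top_n = 20) {
  scheme <- .as_scheme(scheme)
  sc <- .hit_scores(proteome_a, proteome_b, scheme, prefilter, k, top_n)
  empty <- data.frame(protein_id_a = character(0), protein_id_b = character(0),
                      identity = numeric(0), coverage_shorter = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sc) == 0) return(empty)
  ba <- .best_by(sc, "i", "j", names(proteome_b))  # a-query -> b index
  bb <- .best_by(sc, "j", "i", names(proteome_a))  # b-query -> a index
  qa <- as.integer(names(ba))
  mutual <- !is.na(bb[as.character(ba)]) & bb[as.character(ba)] == qa
  ia <- qa[mutual]; ib <- unname(ba[mutual])
  if (length(ia) == 0) return(empty)
  st <- cpp_sw_stats_batch(unname(proteome_a), unname(proteome_b), ia, ib,
                           scheme$smat, scheme$alphabet,
                           scheme$gap_open, scheme$gap_extend)
  len_a <- nchar(proteome_a)[ia]
  len_b <- nchar(proteome_b)[ib]
  shorter <- pmin(len_a, len_b)
  alen_short <- ifelse(len_a <= len_b, st[, "alen_a"], st[, "alen_b"])
  out <- data.frame(protein_id_a = names(proteome_a)[ia],
                    protein_id_b = names(proteome_b)[ib],
                    identity = st[, "pid"],
                    coverage_shorter = alen_short / shorter,
                    score = st[, "score"], stringsAsFactors = FALSE)
  out[order(out$protein_id_a), , drop = FALSE]
}

#' Homolog filters: coverage and identity
#'
#' Retains pairs aligned over at least 70 % of the shorter sequence with
#' identity strictly above 30 % (both thresholds configurable).
#'
#' @param pairs data frame as returned by [reciprocal_best_hits()].
#' @param min_coverage minimum `coverage_shorter` (inclusive).
#' @param min_identity identity threshold (exclusive: retained if
#'   `identity > min_identity`).
#' @return the retained rows.
#' @export
filter_homologs <- function(pairs, min_coverage = 0.70, min_identity = 30) {
  pairs[pairs$coverage_shorter >= min_coverage & pairs$identity > min_identity,
        , drop = FALSE]
}

#' Average amino-acid identity from homolog pairs
#'
#' The unweighted mean identity over homologs, reported only when at least
#' `min_homologs` homologs survive the filters; otherwise the record is
#' flagged discarded and carries no AAI.
#'
#' @param pairs filtered homolog pairs ([filter_homologs()]).
#' @param min_homologs minimum homolog count (default 200).
#' @param genome_a,genome_b optional genome ids recorded in the result.
#' @return one-row data frame: `genome_a`, `genome_b`, `n_homologs`, `aai`
#'   (NA when discarded), `discarded`.
#' @export
compute_aai <- function(pairs, min_homologs = 200,
                        genome_a = NA_character_, genome_b = NA_character_) {
  .chk(is.numeric(min_homologs) && min_homologs >= 1,
       "min_homologs must be >= 1", "invalid_config")
  n <- nrow(pairs)
  discarded <- n < min_homologs
  data.frame(genome_a = genome_a, genome_b = genome_b, n_homologs = n,
             aai = if (discarded) NA_real_ else mean(pairs$identity),
             discarded = discarded, stringsAsFactors = FALSE)
}

#' AAI between two proteomes
#'
#' Convenience wrapper: reciprocal best hits, Smith-Waterman re-alignment,
#' coverage/identity filters, then [compute_aai()].
#'
#' @inheritParams reciprocal_best_hits
#' @inheritParams compute_aai
#' @inheritParams filter_homologs
#' @return as [compute_aai()].
#' @export
aai_between <- function(proteome_a, proteome_b,
                        scheme = scoring_scheme("protein"),
                        min_homologs = 200, min_coverage = 0.70,
                        min_identity = 30,
                        genome_a = NA_character_, genome_b = NA_character_,
                        prefilter = TRUE, k = 4, top_n = 20) {
  rbh <- reciprocal_best_hits(proteome_a, proteome_b, scheme,
                              prefilter = prefilter, k = k, top_n = top_n)
  kept <- filter_homologs(rbh, min_coverage, min_identity)
  compute_aai(kept, min_homologs, genome_a, genome_b)
}

#' Recognize marker genes in a proteome by reciprocal best hit
#'
#' For each reference marker protein, its reciprocal best hit in the genome's
#' proteome, or absence when there is none — the classical way of
#' transferring a reference genome's marker annotation to other genomes.
#'
#' @param genome_proteome named character vector (the genome searched).
#' @param reference_markers named character vector: marker label -> reference
#'   protein sequence.
#' @inheritParams best_hits
#' @return named character vector: marker label -> protein id in the genome;
#'   markers with no reciprocal best hit are absent.
#' @export
find_markers_by_rbh <- function(genome_proteome, reference_markers,
                                scheme = scoring_scheme("protein"),
                                prefilter = TRUE, k = 4, top_n = 20) {
  .chk(length(reference_markers) >= 1, "reference_markers must be nonempty",
       "invalid_input")
  rbh <- reciprocal_best_hits(reference_markers, genome_proteome, scheme,
                              prefilter = prefilter, k = k, top_n = top_n)
  setNames(rbh$protein_id_b, rbh$protein_id_a)
}

#' Presence filter for candidate marker genes
#'
#' Retains genes present in strictly more than `threshold` of genomes
#' (default 90 %).
#'
#' @param presence named numeric vector: gene label -> fraction of genomes
#'   carrying the gene, in `[0, 1]`.
#' @param threshold strict lower bound on the presence fraction.
#' @return character vector of retained gene labels.
#' @export
marker_presence_filter <- function(presence, threshold = 0.90) {
  .chk(all(presence >= 0 & presence <= 1), "presence fractions must be in [0,1]",
       "invalid_input")
  names(presence)[presence > threshold]
}
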