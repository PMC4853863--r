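# Pairwise alignment: thin R interface over the C++ Gotoh kernels.

.check_seq <- function(x, what) {
  .chk(is.character(x) && length(x) == 1 && !is.na(x),
       paste(what, "must be a single character string"), "invalid_input")
  .chk(nzchar(x), paste(what, "must be nonempty"), "invalid_input")
  x
}

.aln_result <- function(raw, a, b, local) {
  n_short <- min(nchar(a), nchar(b))
  pid <- if (raw$n_columns > 0) 100 * raw$n_identical / raw$n_columns else 0
  if (local) {
    alen_short <- if (nchar(a) <= nchar(b)) {
      if (raw$a_end > 0) raw$a_end - raw$a_start + 1 else 0
    } else {
      if (raw$b_end > 0) raw$b_end - raw$b_start + 1 else 0
    }
    cov <- alen_short / n_short
  } else cov <- 1.0
  structure(
    list(aligned_a = raw$aligned_a, aligned_b = raw$aligned_b,
         score = raw$score, percent_identity = pid, coverage_shorter = cov,
         n_identical = raw$n_identical, n_columns = raw$n_columns,
         local = local),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s; score %.4g; identity %.2f%%; coverage %.3f\n",
              if (x$local) "local" else "global", x$score,
              x$percent_identity, x$coverage_shorter))
  if (nchar(x$aligned_a) <= 60) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Optimal global (Needleman-Wunsch) alignment
#'
#' Affine-gap global alignment with end gaps penalized.  Percent identity is
#' the number of identical residue-residue columns divided by the total
#' number of alignment columns (gap columns included).  Traceback ties are
#' broken deterministically, preferring diagonal over up over left.
#'
#' @param a,b nonempty sequences over the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @return an `alignment_result`: `aligned_a`, `aligned_b`, `score`,
#'   `percent_identity` (0-100), `coverage_shorter` (always 1 for global).
#' @examples
#' global_align("ACGT", "ACGA", scoring_scheme("nucleotide"))
#' @export
global_align <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  scheme <- .as_scheme(scheme)
  raw <- cpp_nw_align(.check_seq(a, "a"), .check_seq(b, "b"), scheme$smat,
                      scheme$alphabet, scheme$gap_open, scheme$gap_extend)
  .aln_result(raw, a, b, local = FALSE)
}

#' Optimal local (Smith-Waterman) alignment
#'
#' Affine-gap local alignment.  If no positive-scoring alignment exists the
#' result is the empty alignment with score 0, percent identity 0 and
#' coverage 0.  Percent identity is computed over the aligned columns;
#' `coverage_shorter` is the aligned fraction of the shorter sequence.
#'
#' @inheritParams global_align
#' @return an `alignment_result`.
#' @examples
#' local_align("MMMPQRWWW", "PQR", scoring_scheme("protein"))
#' @export
local_align <- function(a, b, scheme = scoring_scheme("protein")) {
  scheme <- .as_scheme(scheme)
  raw <- cpp_sw_align(.check_seq(a, "a"), .check_seq(b, "b"), scheme$smat,
                      scheme$alphabet, scheme$gap_open, scheme$gap_extend)
  .aln_result(raw, a, b, local = TRUE)
}

#' Maximal percent identity over gene copies
#'
#' Aligns every copy of a gene in one genome against every copy in another
#' (global alignment) and returns the maximal percent identity, the rule used
#' for multi-copy genes such as 16S rRNA.
#'
#' @param copies_a,copies_b nonempty character vectors of copies.
#' @inheritParams global_align
#' @return maximal percent identity (scalar).
#' @export
percent_identity_pairmax <- function(copies_a, copies_b,
                                     scheme = scoring_scheme("nucleotide")) {
  .chk(is.character(copies_a) && length(copies_a) >= 1 && all(nzchar(copies_a)),
       "copies_a must be a nonempty character vector (missing gene?)",
       "missing_gene")
  .chk(is.character(copies_b) && length(copies_b) >= 1 && all(nzchar(copies_b)),
       "copies_b must be a nonempty character vector (missing gene?)",
       "missing_gene")
  scheme <- .as_scheme(scheme)
  combos <- expand.grid(i = seq_along(copies_a), j = seq_along(copies_b))
  res <- cpp_nw_batch(copies_a[combos$i], copies_b[combos$j], scheme$smat,
                      scheme$alphabet, scheme$gap_open, scheme$gap_extend)
  max(100 * res[, "n_identical"] / res[, "n_columns"])
}

# internal: brute-force oracles (exhaustive enumeration), used by the test
# suite as an independent check of the DP kernels
.bf_global_score <- function(a, b, scheme) {
  cpp_bf_global_score(a, b, scheme$smat, scheme$alphabet,
                      scheme$gap_open, scheme$gap_extend)
}
.bf_local_score <- function(a, b, scheme) {
  cpp_bf_local_score(a, b, scheme$smat, scheme$alphabet,
                     scheme$gap_open, scheme$gap_extend)
}
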