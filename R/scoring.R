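#' Alignment scoring scheme
#'
#' Bundles a substitution matrix with affine gap penalties.  A gap run of
#' length L costs `gap_open + L * gap_extend`.  Defaults follow common
#' practice: EMBOSS-needle-like scores for nucleotides (match +5,
#' mismatch -4, gap open 10, gap extend 0.5) and BLAST-like scores for
#' proteins (BLOSUM62, gap open 11, gap extend 1).
#'
#' For nucleotides the alphabet is `ACGTN`; `N` mismatches every letter,
#' including itself.  For proteins the alphabet is that of the Biostrings
#' substitution matrix (the 20 amino acids plus ambiguity letters such as
#' `X`, which score as near-mismatches).
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param matrix protein substitution matrix name (from Biostrings), or a
#'   numeric matrix with identical row/column letter names.
#' @param gap_open,gap_extend nonnegative gap penalties,
#'   `gap_open >= gap_extend`.  Set `gap_extend = gap_open` for linear gaps.
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("nucleotide")
#' scoring_scheme("protein", gap_open = 10, gap_extend = 0.5)
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"),
                           match = 5, mismatch = -4,
                           matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_extend)) gap_extend <- 0.5
    letters4 <- c("A", "C", "G", "T", "N")
    smat <- base::matrix(mismatch, 5, 5, dimnames = list(letters4, letters4))
    diag(smat) <- match
    smat["N", "N"] <- mismatch  # ambiguity codes are mismatches
  } else {
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.character(matrix)) {
      env <- new.env()
      utils::data(list = matrix, package = "Biostrings", envir = env)
      smat <- get(matrix, envir = env)
    } else smat <- matrix
    .chk(is.matrix(smat) && identical(rownames(smat), colnames(smat)),
         "protein substitution matrix must be square with letter dimnames",
         "invalid_config")
    storage.mode(smat) <- "double"
  }
  .chk(is.numeric(gap_open) && is.numeric(gap_extend) &&
         gap_open >= gap_extend && gap_extend >= 0,
       "gap penalties must satisfy gap_open >= gap_extend >= 0",
       "invalid_config")
  structure(
    list(kind = kind, smat = smat,
         alphabet = paste(rownames(smat), collapse = ""),
         gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend)),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s; alphabet %s; gap open %g extend %g\n",
              x$kind, x$alphabet, x$gap_open, x$gap_extend))
  invisible(x)
}

.as_scheme <- function(s) {
  .chk(inherits(s, "scoring_scheme"), "expected a scoring_scheme", "invalid_input")
  s
}
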