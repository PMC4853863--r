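# Internal helpers: classed conditions, seed derivation, seeded evaluation.

.err <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("markerAAI_", class), "markerAAI_error")))
}

.chk <- function(cond, msg, class) {
  if (!cond) .err(msg, class)
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer mixing (multiplicative-congruential style) used to
#' give every gene, tree and sampling loop its own independent stream, so that
#' e.g. adding a gene to a simulation does not perturb the sequences of the
#' others.  Results stay below 2^31.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  .chk(is.numeric(master) && length(master) == 1 && is.finite(master),
       "master seed must be a single finite number", "invalid_config")
  .chk(is.numeric(index) && length(index) == 1 && index >= 0,
       "stream index must be a single nonnegative number", "invalid_config")
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(master) %% m) * 48271 %% m
  s <- (s + (index %% m) * 69621) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s)
}

# evaluate expr with a temporary, fully specified RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# canonical unordered pair labels: a < b
.pair_canon <- function(a, b) {
  swap <- a > b
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  list(a = ga, b = gb)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
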