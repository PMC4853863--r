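# Correlation and resampling statistics.

#' Spearman rank correlation
#'
#' Rho on fractional ranks with the t-distribution approximation for the
#' p-value (suitable for the sample sizes used here; the exact permutation
#' null is not computed).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  .chk(length(x) == length(y), "x and y must have equal length", "invalid_input")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  .chk(length(x) >= 3, "insufficient-data: need n >= 3", "insufficient_data")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    .err("undefined-correlation: constant input vector", "undefined_correlation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.4f, p = %.3g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Per-gene identity-vs-AAI correlations split at an AAI threshold
#'
#' For every marker gene, the Spearman correlation between that gene's
#' percent identity and AAI, computed separately for distantly related pairs
#' (AAI < threshold, the "far" side) and closely related pairs
#' (AAI > threshold, the "close" side).  Genes are ordered by decreasing
#' close-side rho.  Sides with fewer than 3 pairs or a constant identity
#' vector yield `NA` with a note rather than an error, so one degenerate
#' gene does not abort a cohort analysis.
#'
#' @param df data frame with columns `gene_label`, `identity`, `aai`
#'   (one row per genome pair per gene).
#' @param threshold AAI split point, percent (default 95).
#' @return data frame `gene_label`, `side` (`"close"`/`"far"`), `rho`, `p`,
#'   `n`, `note`.
#' @export
split_correlations <- function(df, threshold = 95) {
  .chk(threshold > 0 && threshold < 100, "threshold must be in (0,100)",
       "invalid_config")
  .chk(all(c("gene_label", "identity", "aai") %in% names(df)),
       "df must have gene_label, identity, aai", "invalid_input")
  out <- list()
  for (gene in sort(unique(df$gene_label))) {
    sub <- df[df$gene_label == gene & !is.na(df$aai), , drop = FALSE]
    for (side in c("close", "far")) {
      sel <- if (side == "close") sub$aai > threshold else sub$aai < threshold
      xs <- sub$identity[sel]; ys <- sub$aai[sel]
      res <- tryCatch(spearman(xs, ys), markerAAI_error = function(e) e)
      if (inherits(res, "correlation_result")) {
        out[[paste(gene, side)]] <- data.frame(
          gene_label = gene, side = side, rho = res$rho, p = res$p_value,
          n = res$n, note = "", stringsAsFactors = FALSE)
      } else {
        out[[paste(gene, side)]] <- data.frame(
          gene_label = gene, side = side, rho = NA_real_, p = NA_real_,
          n = sum(sel), note = conditionMessage(res), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  close_rho <- res$rho[res$side == "close"][match(res$gene_label,
                                                 res$gene_label[res$side == "close"])]
  res[order(-ifelse(is.na(close_rho), -Inf, close_rho), res$gene_label,
            res$side), , drop = FALSE]
}

#' Binned AAI confidence intervals from genome-disjoint resampling
#'
#' Bins genome pairs by 16S-like percent identity into contiguous half-open
#' bins of `bin_width` percent.  Within each bin, draws `n_samplings`
#' random samples of `sample_size` pairs such that no genome appears twice
#' within a sampling (greedy randomized matching), computes the mean AAI of
#' each sampling, and reports the 2.5th/97.5th percentiles of the sampling
#' means.  Bins that cannot supply `sample_size` genome-disjoint pairs are
#' flagged and report the achieved size; empty bins are flagged `"empty"`.
#'
#' @param df data frame with `genome_a`, `genome_b`, `identity_16s`, `aai`.
#' @param bin_width bin width in identity percent (default 2).
#' @param n_samplings number of random samplings (default 20).
#' @param sample_size genome-disjoint pairs per sampling (default 100).
#' @param seed integer seed (one derived stream per bin and sampling).
#' @return data frame `bin_low`, `bin_high`, `n_pairs`, `ci_low`, `ci_high`,
#'   `n_samplings`, `sample_size`, `achieved`, `flag`.
#' @export
binned_ci <- function(df, bin_width = 2, n_samplings = 20, sample_size = 100,
                      seed = 1) {
  .chk(bin_width > 0, "bin_width must be positive", "invalid_config")
  .chk(all(c("genome_a", "genome_b", "identity_16s", "aai") %in% names(df)),
       "df must have genome_a, genome_b, identity_16s, aai", "invalid_input")
  df <- df[!is.na(df$aai) & !is.na(df$identity_16s), , drop = FALSE]
  origin <- floor(min(df$identity_16s, 100) / bin_width) * bin_width
  lows <- seq(origin, 100, by = bin_width)
  out <- list()
  for (bi in seq_along(lows)) {
    lo <- lows[bi]; hi <- lo + bin_width
    sel <- df$identity_16s >= lo & df$identity_16s < hi
    sub <- df[sel, , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[bi]] <- data.frame(bin_low = lo, bin_high = hi, n_pairs = 0L,
                              ci_low = NA_real_, ci_high = NA_real_,
                              n_samplings = n_samplings,
                              sample_size = sample_size, achieved = 0L,
                              flag = "empty", stringsAsFactors = FALSE)
      next
    }
    means <- numeric(n_samplings)
    achieved <- integer(n_samplings)
    for (s in seq_len(n_samplings)) {
      ord <- .with_seed(derive_seed(seed, 1000 * bi + s),
                        sample.int(nrow(sub)))
      used <- character(0)
      take <- integer(0)
      for (r in ord) {
        ga <- sub$genome_a[r]; gb <- sub$genome_b[r]
        if (ga %in% used || gb %in% used) next
        take <- c(take, r)
        used <- c(used, ga, gb)
        if (length(take) >= sample_size) break
      }
      means[s] <- mean(sub$aai[take])
      achieved[s] <- length(take)
    }
    ci <- unname(quantile(means, c(0.025, 0.975), type = 7))
    out[[bi]] <- data.frame(
      bin_low = lo, bin_high = hi, n_pairs = nrow(sub),
      ci_low = ci[1], ci_high = ci[2], n_samplings = n_samplings,
      sample_size = sample_size, achieved = min(achieved),
      flag = if (min(achieved) < sample_size) "deficit" else "",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
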