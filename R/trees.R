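# UPGMA tree construction and Robinson-Foulds split distance.

#' Distance matrix from percent identities or AAI
#'
#' Entries are `1 - value/100`, the conventional conversion of a percent
#' identity (or AAI) into a dissimilarity.
#'
#' @param genome_a,genome_b character vectors of pair members.
#' @param value percent identities or AAIs, in `[0, 100]`.
#' @param genomes optional label set; defaults to all genomes seen.
#' @param on_missing `"error"` to fail on a missing pair value
#'   (incomplete-matrix), `"drop"` to greedily drop the genomes with most
#'   missing pairs until the matrix is complete.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
identity_to_distance <- function(genome_a, genome_b, value, genomes = NULL,
                                 on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.null(genomes)) genomes <- sort(unique(c(genome_a, genome_b)))
  d <- matrix(NA_real_, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  diag(d) <- 0
  sel <- genome_a %in% genomes & genome_b %in% genomes & !is.na(value)
  ia <- match(genome_a[sel], genomes); ib <- match(genome_b[sel], genomes)
  d[cbind(ia, ib)] <- 1 - value[sel] / 100
  d[cbind(ib, ia)] <- 1 - value[sel] / 100
  while (anyNA(d)) {
    if (on_missing == "error")
      .err("incomplete-matrix: missing pair value(s)", "incomplete_matrix")
    miss <- rowSums(is.na(d))
    worst <- names(which.max(miss))
    keep <- setdiff(rownames(d), worst)
    d <- d[keep, keep, drop = FALSE]
    if (nrow(d) < 2)
      .err("incomplete-matrix: fewer than 2 genomes with complete values",
           "incomplete_matrix")
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Standard agglomeration with size-weighted arithmetic-mean linkage; the
#' height of a merge is half the cluster distance, so the result is
#' ultrametric.  Ties are broken deterministically by the lexicographically
#' smallest merged label pair.  Merges at (numerically) equal heights remain
#' binary; use `collapse = TRUE` to collapse zero-length internal edges into
#' multifurcations (e.g. for split counting when the input carries no
#' signal).
#'
#' @param d symmetric nonnegative matrix with zero diagonal (labels as
#'   dimnames), or a `dist`.
#' @param collapse collapse internal edges shorter than `tol`.
#' @param tol zero-branch tolerance used when `collapse = TRUE`.
#' @return a rooted ultrametric `phylo`.
#' @export
upgma <- function(d, collapse = FALSE, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  .chk(is.matrix(d) && nrow(d) == ncol(d) && nrow(d) >= 2,
       "invalid-matrix: need a square matrix with >= 2 labels", "invalid_matrix")
  .chk(!is.null(rownames(d)), "invalid-matrix: labels required", "invalid_matrix")
  .chk(max(abs(d - t(d))) <= 1e-12 && all(diag(d) == 0) && all(d >= 0),
       "invalid-matrix: must be symmetric, nonnegative, zero diagonal",
       "invalid_matrix")
  labels <- rownames(d)
  n <- length(labels)
  # active clusters: newick fragment, height, size, smallest member label
  frag <- labels; height <- rep(0, n); size <- rep(1L, n); minlab <- labels
  D <- d
  active <- seq_len(n)
  for (step in seq_len(n - 1)) {
    # find min distance among active pairs; ties -> smallest (minlab_i, minlab_j)
    best <- NULL
    for (x in seq_along(active)) {
      for (y in seq.int(x + 1, length.out = max(0, length(active) - x))) {
        i <- active[x]; j <- active[y]
        dij <- D[i, j]
        lab <- sort(c(minlab[i], minlab[j]))
        cand <- list(d = dij, i = i, j = j, lab = lab)
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], h - height[i],
                       frag[j], h - height[j])
    # size-weighted proportional averaging to all other active clusters
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <- (size[i] * D[i, k] + size[j] * D[j, k]) /
        (size[i] + size[j])
    }
    frag[i] <- newfrag
    height[i] <- h
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    active <- setdiff(active, j)
  }
  tree <- ape::read.tree(text = paste0(frag[active], ";"))
  if (collapse) tree <- ape::di2multi(tree, tol = tol)
  tree
}

# non-trivial splits of a tree viewed as unrooted = internal edges after
# unrooting (singleton-free)
.n_splits <- function(tree) {
  if (length(tree$tip.label) < 4) return(0L)
  tr <- ape::unroot(ape::collapse.singles(tree))
  sum(tr$edge[, 2] > length(tr$tip.label))
}

#' Robinson-Foulds split distance between two trees
#'
#' Trees are compared as unrooted.  `raw` counts the non-trivial
#' bipartitions present in exactly one tree; `normalized` divides by the
#' total number of non-trivial bipartitions in both trees, giving a value in
#' `[0, 1]` comparable across lineages of different sizes.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return list with `raw` (integer) and `normalized` (real).
#' @export
split_distance <- function(t1, t2) {
  .chk(inherits(t1, "phylo") && inherits(t2, "phylo"),
       "both arguments must be phylo objects", "invalid_input")
  if (!setequal(t1$tip.label, t2$tip.label))
    .err("incompatible-trees: leaf label sets differ", "incompatible_trees")
  ns <- .n_splits(t1) + .n_splits(t2)
  if (length(t1$tip.label) < 4 || ns == 0)
    return(list(raw = 0L, normalized = 0))
  raw <- suppressMessages(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                                            check.labels = TRUE))
  list(raw = as.integer(raw), normalized = raw / ns)
}

# independent brute-force bipartition comparison (test oracle): enumerate the
# non-trivial splits of each unrooted tree as canonical leaf subsets
.splits_of <- function(tree) {
  tr <- ape::unroot(ape::collapse.singles(tree))
  tips <- sort(tr$tip.label)
  ntip <- length(tips)
  if (ntip < 4) return(character(0))
  internal <- tr$edge[tr$edge[, 2] > length(tr$tip.label), 2]
  out <- character(0)
  for (nd in internal) {
    clade <- ape::extract.clade(tr, nd)$tip.label
    side <- sort(clade)
    other <- sort(setdiff(tips, side))
    if (length(side) < 2 || length(other) < 2) next
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

.bf_split_distance <- function(t1, t2) {
  s1 <- .splits_of(t1); s2 <- .splits_of(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
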