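# Genome-evolution simulator: Yule genealogies, K-state Jukes-Cantor
# substitution, lineage-structured cohorts with known per-gene rates.

#' Simulation configuration
#'
#' Defines a cohort of related genomes: a lineage-structured clock genealogy,
#' a set of marker genes evolving as nucleotide sequences (one slow-evolving,
#' possibly multi-copy, 16S-like marker among them), and a set of background
#' protein-coding genes evolving as amino-acid sequences.  Identical configs
#' (including the seed) yield byte-identical simulated datasets.
#'
#' The default configuration is the package's desk-scale cohort: 3 lineages
#' of 8 genomes, 30 markers whose rate multipliers are log-spaced from 0.05 to
#' 3.0 around a slow (0.02) two-copy 16S-like gene, and 120 background genes
#' with rates lognormal around 0.08, on a genealogy whose root-to-leaf depth
#' is 5 expected substitutions per site at the base rate with within-lineage
#' crowns of depth 0.15.  This spans intra-lineage divergences where fast
#' markers carry the most signal up to cross-lineage divergences where fast
#' markers are saturated and only slow genes remain informative (see the
#' methods vignette for the closed-form rationale).
#'
#' @param n_lineages number of lineages (clades joined by a deep backbone).
#' @param genomes_per_lineage genomes in each lineage crown.
#' @param n_markers number of marker genes including the 16S-like one.
#' @param n_background_genes number of background protein-coding genes.
#' @param marker_length_nt marker gene length, nucleotides (>= 300).
#' @param len_16s_nt length of the 16S-like marker (default 1500, within the
#'   conventional 1000-1800 bp window).
#' @param protein_length_aa background protein length, amino acids (>= 50).
#' @param tree_depth root-to-leaf depth of the genealogy, expected
#'   substitutions per site at the base rate.
#' @param crown_depth root-to-leaf depth of each within-lineage crown.
#' @param backbone_span fraction range of `tree_depth` in which non-root
#'   backbone join heights are drawn (stratified uniforms).
#' @param crown_min_gap_frac crown topologies are resampled until all
#'   internal node heights are separated by at least this fraction of
#'   `crown_depth`, so that simulated strains sit at mutually resolvable
#'   divergences (0 disables the rejection step).
#' @param n_16s_copies copies of the 16S-like marker per genome.
#' @param copy_divergence extra substitutions/site applied independently to
#'   each 16S-like copy within a genome.
#' @param rate_multipliers optional named vector of per-gene rate
#'   multipliers; by default the slow16s gets 0.02, markers are log-spaced
#'   0.05-3.0 (reaching down to near-16S conservation, as ribosomal
#'   proteins do) and background genes are lognormal(meanlog = log 0.08,
#'   sdlog = 0.15), drawn from a seed-derived stream.
#' @param presence_prob per-gene per-genome retention probability in (0, 1];
#'   the 16S-like marker is always present.
#' @param seed master seed; every stochastic component derives its own
#'   stream from it.
#' @return an object of class `sim_config`.
#' @seealso [generate_dataset()]
#' @export
sim_config <- function(n_lineages = 3, genomes_per_lineage = 8,
                       n_markers = 30, n_background_genes = 120,
                       marker_length_nt = 750, len_16s_nt = 1500,
                       protein_length_aa = 120,
                       tree_depth = 5, crown_depth = 0.15,
                       backbone_span = c(0.5, 0.7),
                       crown_min_gap_frac = 0,
                       n_16s_copies = 2, copy_divergence = 0.005,
                       rate_multipliers = NULL,
                       presence_prob = 0.98, seed = 1) {
  .chk(n_lineages >= 1, "n_lineages must be >= 1", "invalid_config")
  .chk(genomes_per_lineage >= 1, "genomes_per_lineage must be >= 1", "invalid_config")
  n_genomes <- n_lineages * genomes_per_lineage
  .chk(n_genomes >= 2, "need at least 2 genomes", "invalid_config")
  .chk(n_markers >= 1, "n_markers must be >= 1", "invalid_config")
  .chk(n_background_genes >= 1, "n_background_genes must be >= 1", "invalid_config")
  .chk(marker_length_nt >= 300, "marker_length_nt must be >= 300", "invalid_config")
  .chk(protein_length_aa >= 50, "protein_length_aa must be >= 50", "invalid_config")
  .chk(tree_depth >= 0, "tree_depth must be nonnegative", "invalid_config")
  .chk(crown_depth >= 0 && (n_lineages == 1 || crown_depth <= tree_depth),
       "crown_depth must be in [0, tree_depth]", "invalid_config")
  .chk(length(backbone_span) == 2 && all(backbone_span > 0) &&
         all(backbone_span <= 1) && backbone_span[1] <= backbone_span[2],
       "backbone_span must be increasing fractions in (0, 1]", "invalid_config")
  .chk(n_16s_copies >= 1, "n_16s_copies must be >= 1", "invalid_config")
  .chk(copy_divergence >= 0, "copy_divergence must be nonnegative", "invalid_config")
  .chk(presence_prob > 0 && presence_prob <= 1,
       "presence_prob must be in (0, 1]", "invalid_config")
  .chk(crown_min_gap_frac >= 0 && crown_min_gap_frac < 1,
       "crown_min_gap_frac must be in [0, 1)", "invalid_config")
  .chk(is.numeric(seed) && length(seed) == 1, "seed must be an integer", "invalid_config")

  marker_labels <- c("slow16s",
                     if (n_markers > 1)
                       sprintf("marker%02d", seq_len(n_markers - 1)))
  bg_labels <- sprintf("bg%03d", seq_len(n_background_genes))
  if (is.null(rate_multipliers)) {
    mk <- if (n_markers > 1) {
      if (n_markers == 2) 1.0
      else exp(seq(log(0.05), log(3.0), length.out = n_markers - 1))
    } else numeric(0)
    bg <- .with_seed(derive_seed(seed, 9001),
                     rlnorm(n_background_genes, meanlog = log(0.08), sdlog = 0.15))
    rate_multipliers <- setNames(c(0.02, mk, bg), c(marker_labels, bg_labels))
  }
  all_labels <- c(marker_labels, bg_labels)
  .chk(all(all_labels %in% names(rate_multipliers)),
       "rate_multipliers must have an entry for every marker and background gene",
       "invalid_config")
  .chk(all(rate_multipliers[all_labels] >= 0),
       "rate multipliers must be nonnegative", "invalid_config")
  structure(
    list(n_genomes = n_genomes, n_lineages = n_lineages,
         genomes_per_lineage = genomes_per_lineage,
         n_markers = n_markers, n_background_genes = n_background_genes,
         marker_length_nt = as.integer(marker_length_nt),
         len_16s_nt = as.integer(len_16s_nt),
         protein_length_aa = as.integer(protein_length_aa),
         tree_depth = tree_depth, crown_depth = crown_depth,
         backbone_span = backbone_span,
         crown_min_gap_frac = crown_min_gap_frac,
         n_16s_copies = as.integer(n_16s_copies),
         copy_divergence = copy_divergence,
         marker_labels = marker_labels, bg_labels = bg_labels,
         rate_multipliers = rate_multipliers[all_labels],
         presence_prob = presence_prob, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d genomes (%d lineages x %d), %d markers ",
                     "(16S-like: %d nt, %d copies), %d background genes; ",
                     "depth %g (crown %g); presence %g; seed %d\n"),
              x$n_genomes, x$n_lineages, x$genomes_per_lineage, x$n_markers,
              x$len_16s_nt, x$n_16s_copies, x$n_background_genes,
              x$tree_depth, x$crown_depth, x$presence_prob, x$seed))
  invisible(x)
}

#' Sample a random ultrametric (Yule) tree
#'
#' Pure-birth branching via [ape::rphylo()], with branch lengths rescaled so
#' that every root-to-leaf path equals `depth` exactly.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param depth root-to-leaf path length, expected substitutions per site.
#' @param seed integer seed.
#' @param labels optional leaf labels (default `g01`, `g02`, ...).
#' @return a rooted binary ultrametric `phylo` object.
#' @export
sample_tree <- function(n_taxa, depth, seed = 1, labels = NULL) {
  .chk(is.numeric(n_taxa) && n_taxa >= 2, "n_taxa must be >= 2", "invalid_config")
  .chk(depth >= 0, "depth must be nonnegative", "invalid_config")
  tr <- .with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tr <- .rescale_ultrametric(tr, depth)
  tr$tip.label <- if (is.null(labels)) sprintf("g%02d", seq_len(n_taxa)) else labels
  tr
}

# rescale so that every tip sits exactly at `depth` from the root
.rescale_ultrametric <- function(tr, depth) {
  nd <- ape::node.depth.edgelength(tr)
  ntip <- length(tr$tip.label)
  maxd <- max(nd[seq_len(ntip)])
  if (maxd > 0) tr$edge.length <- tr$edge.length * (depth / maxd)
  # absorb any floating-point drift into the terminal edges
  nd <- ape::node.depth.edgelength(tr)
  term <- match(seq_len(ntip), tr$edge[, 2])
  tr$edge.length[term] <- tr$edge.length[term] + (depth - nd[seq_len(ntip)])
  if (depth == 0) tr$edge.length[] <- 0
  tr
}

#' Evolve a sequence under a K-state Jukes-Cantor process
#'
#' Each site experiences a substitution event with probability
#' `1 - exp(-(K/(K-1)) * d)` where `d` is the branch length in expected
#' substitutions per site; an event replaces the letter with a uniform draw
#' from the K-letter alphabet (possibly the same letter).  The expected
#' fraction of identical sites after divergence `d` is therefore
#' `1/K + (K-1)/K * exp(-(K/(K-1)) d)`.
#'
#' @param parent nonempty sequence (character scalar).
#' @param branch_subs_per_site nonnegative branch length.
#' @param alphabet_size 4 (nucleotides ACGT) or 20 (amino acids).
#' @param seed optional integer; when given, an isolated stream is used and
#'   the caller's RNG state is untouched.
#' @return the child sequence, same length as `parent`.
#' @export
evolve_sequence <- function(parent, branch_subs_per_site, alphabet_size = 4,
                            seed = NULL) {
  .check_seq(parent, "parent")
  .chk(is.numeric(branch_subs_per_site) && branch_subs_per_site >= 0,
       "branch length must be nonnegative", "invalid_config")
  .chk(alphabet_size %in% c(4, 20), "alphabet_size must be 4 or 20", "invalid_config")
  alpha <- if (alphabet_size == 4) .NT else .AA
  x <- strsplit(parent, "", fixed = TRUE)[[1]]
  idx <- match(x, alpha)
  .chk(!anyNA(idx), "parent contains letters outside the alphabet", "invalid_input")
  run <- function() paste(alpha[.evolve_int(idx, branch_subs_per_site,
                                            alphabet_size)], collapse = "")
  if (is.null(seed)) run() else .with_seed(seed, run())
}

# integer-coded JC step; uses the current RNG stream
.evolve_int <- function(idx, d, K) {
  if (d == 0) return(idx)
  p_event <- 1 - exp(-(K / (K - 1)) * d)
  hit <- runif(length(idx)) < p_event
  n <- sum(hit)
  if (n > 0) idx[hit] <- sample.int(K, n, replace = TRUE)
  idx
}

#' Expected site identity under the K-state Jukes-Cantor model
#'
#' @param d divergence, expected substitutions per site.
#' @param K alphabet size (4 or 20).
#' @return expected fraction of identical sites, in `[1/K, 1]`.
#' @export
jc_expected_identity <- function(d, K = 4) {
  1 / K + (K - 1) / K * exp(-(K / (K - 1)) * d)
}

# ---------------------------------------------------------------------------
# Lineage-structured genealogy: per-lineage Yule crowns joined by a Yule
# backbone whose non-root node heights are stratified uniforms inside
# backbone_span * tree_depth; the root sits at tree_depth.
.build_genealogy <- function(config) {
  L <- config$n_lineages
  gpl <- config$genomes_per_lineage
  lineage_ids <- sprintf("L%d", seq_len(L))
  crowns <- vector("list", L)
  for (l in seq_len(L)) {
    labels <- sprintf("%s_g%02d", lineage_ids[l], seq_len(gpl))
    if (gpl == 1) {
      crowns[[l]] <- list(newick = labels, height = 0)
    } else {
      tr <- .sample_crown(gpl, config$crown_depth, config$crown_min_gap_frac,
                          config$seed, l, labels)
      nwk <- ape::write.tree(tr, digits = 12)
      crowns[[l]] <- list(newick = sub(";$", "", nwk), height = config$crown_depth)
    }
  }
  if (L == 1) {
    tree <- ape::read.tree(text = paste0(crowns[[1]]$newick, ";"))
  } else {
    # join heights: root at tree_depth, others stratified in backbone_span
    n_join <- L - 1
    hs <- if (n_join > 1) {
      u <- .with_seed(derive_seed(config$seed, 51), runif(n_join - 1))
      lo <- config$backbone_span[1] * config$tree_depth
      hi <- config$backbone_span[2] * config$tree_depth
      brk <- lo + (hi - lo) * (seq_len(n_join - 1) - u) / (n_join - 1)
      sort(brk)
    } else numeric(0)
    hs <- c(hs, config$tree_depth)
    clusters <- crowns
    u_join <- .with_seed(derive_seed(config$seed, 52), runif(n_join))
    for (k in seq_len(n_join)) {
      # Yule-style coalescence: join the first cluster with a stream-chosen
      # other one at height hs[k]
      n_other <- length(clusters) - 1
      other <- 2 + min(floor(u_join[k] * n_other), n_other - 1)
      h <- hs[k]
      c1 <- clusters[[1]]; c2 <- clusters[[other]]
      nwk <- sprintf("(%s:%.12g,%s:%.12g)", c1$newick, h - c1$height,
                     c2$newick, h - c2$height)
      clusters[[1]] <- list(newick = nwk, height = h)
      clusters[[other]] <- NULL
    }
    tree <- ape::read.tree(text = paste0(clusters[[1]]$newick, ";"))
  }
  lineages <- setNames(rep(lineage_ids, each = gpl),
                       unlist(lapply(seq_len(L), function(l)
                         sprintf("%s_g%02d", lineage_ids[l], seq_len(gpl)))))
  list(tree = tree, lineages = lineages)
}

# Yule crown with internal node heights separated by >= min_gap_frac of the
# crown depth (rejection sampling with a deterministic retry stream)
.sample_crown <- function(n_taxa, depth, min_gap_frac, seed, lineage_index,
                          labels) {
  for (try in 0:499) {
    tr <- sample_tree(n_taxa, depth,
                      seed = derive_seed(seed, 1000 + 500 * lineage_index + try),
                      labels = labels)
    if (min_gap_frac == 0 || depth == 0) return(tr)
    nd <- ape::node.depth.edgelength(tr)
    hts <- sort(nd[(n_taxa + 1):(n_taxa + tr$Nnode)])
    if (length(hts) < 2 || min(diff(hts)) >= min_gap_frac * depth) return(tr)
  }
  tr  # fall back to the last draw rather than loop forever
}

# evolve one gene along the tree; returns named character vector of tip
# sequences (integer-coded internally).  Uses the current RNG stream.
.evolve_gene_on_tree <- function(tree, length_sites, rate, K) {
  alpha <- if (K == 4) .NT else .AA
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- sample.int(K, length_sites, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    d <- tr$edge.length[e] * rate
    seqs[[child]] <- .evolve_int(seqs[[par]], d, K)
  }
  tips <- lapply(seq_len(ntip), function(i)
    paste(alpha[seqs[[i]]], collapse = ""))
  setNames(unlist(tips), tr$tip.label)
}

#' Simulate a cohort of genomes and write it to disk
#'
#' Generates the genealogy, evolves every gene along it (markers as
#' nucleotide sequences, background genes as amino-acid sequences; each
#' gene's branch lengths are the genealogy's times that gene's rate
#' multiplier), applies per-gene per-genome absence with probability
#' `1 - presence_prob` (the 16S-like marker is always present), produces
#' `n_16s_copies` independently diverged copies of the 16S-like marker per
#' genome, and writes the cohort in the layout consumed by [load_cohort()]:
#'
#' * `markers/<genome>.fna` — marker nucleotide FASTA, headers
#'   `<genome>|<gene>|<copy>`
#' * `proteome/<genome>.faa` — background-gene amino-acid FASTA
#' * `annotations.tsv` — genome_id, gene_label, copy_id, sequence_id
#' * `lineages.tsv` — genome_id, lineage
#' * `true_tree.nwk`, `true_rates.tsv` — the generative ground truth
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the ground truth: `true_tree` (`phylo`), `true_rates`
#'   (named vector), `pairwise_path_lengths` (symmetric matrix of
#'   genealogical distances), `lineages` (named vector).
#' @export
generate_dataset <- function(config, out_dir) {
  .chk(inherits(config, "sim_config"), "config must be a sim_config", "invalid_config")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    .err(paste("cannot write to", out_dir), "io_error")
  for (sub in c("markers", "proteome"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)

  gen <- .build_genealogy(config)
  tree <- gen$tree
  genomes <- sort(tree$tip.label)
  rates <- config$rate_multipliers

  # per-genome sequence stores
  marker_seqs <- list()   # [[genome]][[gene]] = named character vector of copies
  proteome_seqs <- list() # [[genome]] = named character vector
  for (g in genomes) { marker_seqs[[g]] <- list(); proteome_seqs[[g]] <- character(0) }

  all_genes <- c(config$marker_labels, config$bg_labels)
  for (gi in seq_along(all_genes)) {
    gene <- all_genes[gi]
    is_marker <- gene %in% config$marker_labels
    is_16s <- identical(gene, "slow16s")
    K <- if (is_marker) 4L else 20L
    len <- if (is_16s) config$len_16s_nt
           else if (is_marker) config$marker_length_nt
           else config$protein_length_aa
    .with_seed(derive_seed(config$seed, 100 + gi), {
      tips <- .evolve_gene_on_tree(tree, len, rates[[gene]], K)
      present <- if (is_16s) rep(TRUE, length(genomes))
                 else runif(length(genomes)) < config$presence_prob
      names(present) <- genomes
      for (g in genomes) {
        if (!present[[g]]) next
        if (is_16s) {
          alpha <- .NT
          base <- match(strsplit(tips[[g]], "", fixed = TRUE)[[1]], alpha)
          copies <- vapply(seq_len(config$n_16s_copies), function(cc)
            paste(alpha[.evolve_int(base, config$copy_divergence, 4L)],
                  collapse = ""), character(1))
          marker_seqs[[g]][[gene]] <- setNames(copies, seq_along(copies))
        } else if (is_marker) {
          marker_seqs[[g]][[gene]] <- setNames(tips[[g]], "1")
        } else {
          proteome_seqs[[g]][[gene]] <- tips[[g]]
        }
      }
    })
  }

  # write FASTAs and tables
  ann <- list()
  for (g in genomes) {
    recs <- character(0)
    for (gene in names(marker_seqs[[g]])) {
      copies <- marker_seqs[[g]][[gene]]
      ids <- sprintf("%s|%s|%s", g, gene, names(copies))
      recs[ids] <- unname(copies)
      ann[[length(ann) + 1]] <- data.frame(
        genome_id = g, gene_label = gene, copy_id = names(copies),
        sequence_id = ids, stringsAsFactors = FALSE)
    }
    write_fasta(recs, file.path(out_dir, "markers", paste0(g, ".fna")))
    prot <- proteome_seqs[[g]]
    names(prot) <- sprintf("%s|%s|1", g, names(prot))
    write_fasta(prot, file.path(out_dir, "proteome", paste0(g, ".faa")))
  }
  ann <- do.call(rbind, ann)
  .write_tsv(ann, file.path(out_dir, "annotations.tsv"))
  .write_tsv(data.frame(genome_id = names(gen$lineages),
                        lineage = unname(gen$lineages))[order(names(gen$lineages)), ],
             file.path(out_dir, "lineages.tsv"))
  write_newick(tree, file.path(out_dir, "true_tree.nwk"))
  .write_tsv(data.frame(gene_label = names(rates), multiplier = unname(rates)),
             file.path(out_dir, "true_rates.tsv"))

  paths <- ape::cophenetic.phylo(tree)
  paths <- paths[genomes, genomes]
  invisible(structure(
    list(true_tree = tree, true_rates = rates,
         pairwise_path_lengths = paths, lineages = gen$lineages),
    class = "ground_truth"))
}
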