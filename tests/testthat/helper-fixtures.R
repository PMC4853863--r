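# Shared fixtures: schemes, random sequences, small simulated cohorts.

nt_scheme <- scoring_scheme("nucleotide")
aa_scheme <- scoring_scheme("protein")

rand_nt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

rand_aa <- function(n, len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}

# mutate a sequence at exactly k positions (guaranteed different letters)
mutate_at <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(x), k)
  for (p in pos) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
  paste(x, collapse = "")
}

# small cohort for io/pipeline tests: quick to simulate and analyze
tiny_config <- function(seed = 1, ...) {
  args <- list(n_lineages = 2, genomes_per_lineage = 4, n_markers = 6,
               n_background_genes = 30, marker_length_nt = 300,
               len_16s_nt = 1000, protein_length_aa = 60,
               tree_depth = 3, crown_depth = 0.15, n_16s_copies = 2,
               presence_prob = 1, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

tiny_pipeline_config <- function(seed = 1, ...) {
  desk_pipeline_config(seed = seed, min_homologs = 20, ...)
}

simulate_tiny <- function(seed = 1, dir = tempfile("cohort"), ...) {
  gt <- generate_dataset(tiny_config(seed, ...), dir)
  list(dir = dir, gt = gt, cohort = load_cohort(dir))
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  structure(unname(tools::md5sum(files)),
            names = sub(paste0("^", dir, "/?"), "", files))
}
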