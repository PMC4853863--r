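# Readers/writers: FASTA (Biostrings), Newick (ape), cohort directories.

#' Read a FASTA file
#'
#' Sequence ids are the header token up to the first whitespace; sequences
#' are uppercased.  Malformed records (sequence before any header, empty
#' sequences) raise a parse error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  .chk(file.exists(path), paste("no such file:", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank)) {
    first <- nonblank[1]
    if (!startsWith(lines[first], ">"))
      .err(sprintf("parse-error at line %d of %s: sequence data before any '>' header",
                   first, path), "parse_error")
    hdr <- which(startsWith(lines, ">"))
    ends <- c(hdr[-1] - 1, length(lines))
    for (i in seq_along(hdr)) {
      body <- lines[seq.int(hdr[i] + 1, length.out = max(0, ends[i] - hdr[i]))]
      if (!any(nzchar(trimws(body))))
        .err(sprintf("parse-error at line %d of %s: record '%s' has an empty sequence",
                     hdr[i], path, sub("^>", "", lines[hdr[i]])), "parse_error")
    }
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.check_alphabet <- function(seqs, allowed, what, where) {
  letters_seen <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  bad <- setdiff(letters_seen, allowed)
  .chk(length(bad) == 0,
       sprintf("invalid %s letters %s in %s", what,
               paste(bad, collapse = ","), where), "parse_error")
}

#' Load a cohort directory
#'
#' Expects the layout written by [generate_dataset()]: `markers/<genome>.fna`,
#' `proteome/<genome>.faa`, `annotations.tsv` (genome_id, gene_label,
#' copy_id, sequence_id), `lineages.tsv` (genome_id, lineage).  Annotations
#' are cross-checked against FASTA headers: annotated-but-missing sequences
#' are errors; unannotated extra sequences are warnings and are ignored.
#' Alphabets are validated (`ACGTN` for markers, 20 amino acids plus `X` for
#' proteomes).
#'
#' @param dir cohort directory.
#' @return an object of class `cohort`: a list with `genomes` (named list of
#'   `genome_record`s, each holding `genome_id`, `markers` — a named list of
#'   copy vectors —, `proteome` and `lineage`), `annotations` and `lineages`.
#' @export
load_cohort <- function(dir) {
  need <- c("annotations.tsv", "lineages.tsv", "markers", "proteome")
  for (f in need)
    .chk(file.exists(file.path(dir, f)),
         paste("layout-error: missing", f, "in", dir), "layout_error")
  ann <- .read_tsv(file.path(dir, "annotations.tsv"))
  .chk(all(c("genome_id", "gene_label", "copy_id", "sequence_id") %in% names(ann)),
       "layout-error: annotations.tsv lacks required columns", "layout_error")
  lin <- .read_tsv(file.path(dir, "lineages.tsv"))
  .chk(all(c("genome_id", "lineage") %in% names(lin)),
       "layout-error: lineages.tsv lacks required columns", "layout_error")
  lineages <- setNames(lin$lineage, lin$genome_id)

  genomes <- list()
  for (g in sort(unique(lin$genome_id))) {
    mpath <- file.path(dir, "markers", paste0(g, ".fna"))
    ppath <- file.path(dir, "proteome", paste0(g, ".faa"))
    .chk(file.exists(mpath), paste("layout-error: missing", mpath), "layout_error")
    .chk(file.exists(ppath), paste("layout-error: missing", ppath), "layout_error")
    mseq <- read_fasta(mpath)
    pseq <- read_fasta(ppath)
    .check_alphabet(mseq, .NT_OK, "nucleotide", mpath)
    .check_alphabet(pseq, .AA_OK, "amino-acid", ppath)
    ga <- ann[ann$genome_id == g, , drop = FALSE]
    missing <- setdiff(ga$sequence_id, names(mseq))
    if (length(missing))
      .err(paste("annotated sequence(s) missing from FASTA:",
                 paste(missing, collapse = ", ")), "layout_error")
    extra <- setdiff(names(mseq), ga$sequence_id)
    if (length(extra))
      warning(sprintf("genome %s: ignoring %d unannotated marker record(s): %s",
                      g, length(extra), paste(extra, collapse = ", ")),
              call. = FALSE)
    markers <- split(setNames(unname(mseq[ga$sequence_id]), ga$copy_id),
                     ga$gene_label)
    prot_names <- vapply(strsplit(names(pseq), "|", fixed = TRUE), `[`,
                         character(1), 2)
    genomes[[g]] <- structure(
      list(genome_id = g, markers = markers,
           proteome = setNames(unname(pseq), prot_names),
           lineage = unname(lineages[g])),
      class = "genome_record")
  }
  structure(list(genomes = genomes, annotations = ann, lineages = lineages),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d genomes, %d lineages, %d annotated marker genes\n",
              length(x$genomes), length(unique(x$lineages)),
              length(unique(x$annotations$gene_label))))
  invisible(x)
}

#' Write / read a tree in Newick format
#'
#' Branch lengths are serialized with 10 significant digits, so a round trip
#' preserves split structure exactly and depths to within 1e-9.  Labels
#' containing Newick structural characters are rejected.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` its path, invisibly.
#' @export
write_newick <- function(tree, path) {
  .chk(inherits(tree, "phylo"), "tree must be a phylo object", "invalid_input")
  bad <- grepl("[][(),:;' ]", tree$tip.label)
  .chk(!any(bad),
       paste("labels restricted: no Newick structural characters allowed:",
             paste(tree$tip.label[bad], collapse = ", ")), "invalid_input")
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  .chk(file.exists(path), paste("no such file:", path), "io_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    .err(paste("parse-error: unbalanced parentheses in", path), "parse_error")
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) .err(paste("parse-error: cannot parse Newick in", path),
                        "parse_error")
  tr
}
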