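Package: markerAAI
Title: Marker-Gene Conservation and Genome-Wide Amino-Acid Identity in
    Prokaryotic Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking which marker genes best predict genome-wide
    similarity between related prokaryotic strains.  Implements average
    amino-acid identity (AAI) from reciprocal-best-hit homologs with
    Smith-Waterman re-alignment and the classical coverage/identity/homolog-count
    filters, Needleman-Wunsch marker-gene percent identities with a
    maximal-identity rule over 16S-like gene copies, per-pair marker
    conservation ranking with lineage averages, UPGMA trees from
    identity-derived distances with Robinson-Foulds split-distance comparison,
    Spearman correlation analyses split at an AAI threshold, genome-disjoint
    binned resampling confidence intervals, and a Jukes-Cantor genome-evolution
    simulator that produces cohorts with known genealogy and known per-gene
    evolutionary rates for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
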