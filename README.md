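# markerAAI

Which marker genes best predict genome-wide similarity between related
prokaryotic strains?

The 16S rRNA gene classifies prokaryotes across the whole tree of life, but
between closely related strains it is too conserved to say anything. This
package implements the complete analysis chain for evaluating marker genes
against genome-wide similarity on any cohort of genomes, together with a
ground-truthed genome-evolution simulator for validating every step:

* **AAI** — average amino-acid identity: homologs between two proteomes are
  reciprocal best hits under Smith–Waterman alignment, kept when aligned
  over ≥ 70 % of the shorter protein with identity > 30 %; AAI is the
  unweighted mean identity over homologs, reported when at least
  `min_homologs` survive (default 200), for pairs whose maximal 16S-like
  identity is ≥ 80 %.
* **Marker identities** — Needleman–Wunsch percent identity per marker gene
  and genome pair, with the maximal identity over 16S copies
  (length-filtered to 1000–1800 bp).
* **Conservation ranks** — within each genome pair carrying all M markers,
  rank 1 = most similar (most conserved) … rank M = least similar;
  fractional ranks on ties; lineage averages over within-lineage pairs.
* **Trees** — UPGMA on 1 − identity/100 or 1 − AAI/100, compared as
  unrooted trees by the Robinson–Foulds split distance (raw and normalized
  by the total number of non-trivial splits).
* **Statistics** — Spearman correlations of each marker's identity with AAI,
  split at AAI = 95 % into closely and distantly related pairs; binned 95 %
  confidence intervals of AAI per 2 % of 16S identity from 20 random
  samplings of 100 genome-disjoint pairs; Spearman correlation between
  lineage-average conservation rank and the normalized split distance of
  each marker's tree to the AAI tree.
* **Simulator** — lineage-structured Yule genealogies with K-state
  Jukes–Cantor sequence evolution and known per-gene rates, emitting the
  exact cohort layout the pipeline consumes.

The alignment kernels (affine-gap Needleman–Wunsch and Smith–Waterman) are
implemented in C++ inside the package, so the pipeline has no external
binary dependencies and is exactly reproducible; the test suite checks them
against exhaustive enumeration oracles and against Biostrings.

## Worked example

Simulate the default desk-scale cohort (3 lineages × 8 genomes, 30 markers
spanning rate multipliers 0.05–3.0 around a slow two-copy 16S-like gene, 120
background genes) and run the full analysis:

```r
library(markerAAI)

gt <- generate_dataset(sim_config(seed = 1), "cohort")
res <- run_all(load_cohort("cohort"), desk_pipeline_config(seed = 1), "run")
report("run")
```

which prints (seed 1):

```
markerAAI pipeline summary for run
genomes: 24; pairs: 276; passing 16S >= threshold: 276
AAI records: 276 analyzable, 0 discarded (min homolog filter)
close-side (AAI > threshold) correlation: best marker27 (rho 0.922); slow16s position 28 of 30
lineage L1: rank vs split-distance rho -0.303 (p 0.11, n 29)
lineage L2: rank vs split-distance rho -0.700 (p 2.3e-05, n 29)
lineage L3: rank vs split-distance rho -0.693 (p 3e-05, n 29)
pooled rank vs split-distance rho -0.562 (p 1.5e-08, n 87)
gene-averaged (across lineages) rank vs split-distance rho -0.743 (p 3.9e-06, n 29)
```

Reading the outputs: between closely related genomes (AAI > 95 %) the
16S-like gene is one of the *worst* predictors of AAI (position 28 of 30
markers), while between distant genomes (AAI < 95 %) it is among the best —
`res$correlations` holds both sides for every marker. The negative
rank-vs-split-distance correlations say that the *less* conserved a marker
is within a lineage (higher average rank), the closer its UPGMA tree is to
the AAI tree; `res$rank_split` also contains the per-gene cross-lineage
average ("gene_avg"), the headline version of that statistic. All stage
tables are written as TSV into the run directory (`marker_identity.tsv`,
`aai.tsv`, `correlations.tsv`, `binned_ci.tsv`, `lineage_ranks.tsv`,
`split_distances.tsv`, `rank_split_correlation.tsv`, plus Newick trees under
`trees/`).

A thin command-line front end with `simulate`, `run` and `report`
subcommands ships as `inst/cli/markeraai.R` (after installation:
`system.file("cli", "markeraai.R", package = "markerAAI")`):

```sh
Rscript inst/cli/markeraai.R simulate --out cohort --seed 1
Rscript inst/cli/markeraai.R run --in cohort --out run --seed 1
Rscript inst/cli/markeraai.R report --in run
```

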