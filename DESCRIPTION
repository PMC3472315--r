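Package: metacompare
Title: Comparative Shotgun Metagenome Analysis of Two Host Gut Microbiotas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative faecal shotgun-metagenome
    analysis between two host groups: construction of a non-redundant gene
    catalogue by single-linkage clustering of predicted ORFs at an identity
    and coverage threshold, identity-threshold read assignment, confidence-
    filtered taxonomic profiling with per-rank abundance tables, two-step
    abundance normalization, rarefaction with Chao1 and Simpson diversity,
    Bray-Curtis ordination (PCoA and NMDS), Wilcoxon rank-sum differential
    abundance with Benjamini-Hochberg FDR control, and best-hit ortholog
    annotation with even-split pathway aggregation. Includes a synthetic
    metagenome generator that emulates pooled-library and single-individual
    sampling designs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
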