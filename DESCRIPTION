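Package: midgutatlas
Title: Compartmentalized Expression Atlas Analysis for the Insect Midgut
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building a tissue expression atlas of the
    pentatomid (stink bug) midgut from a de novo transcriptome: reduction of a
    redundant protein set to unigenes (longest-isoform selection, containment
    deduplication, contaminant filtering), per-compartment expression profiling
    (replicate averaging, presence calls, compartment-overlap partitions,
    top-expressed gene groups, PCA, per-gene one-way ANOVA), fuzzy C-means
    clustering of standardized expression profiles, Fisher's exact gene-set
    enrichment with Benjamini-Hochberg FDR control, and homology-based
    identification of cytochrome P450s and nutrient-transporter families via
    reciprocal-hit voting, hydropathy-based transmembrane segment prediction
    and family length filters. Includes a synthetic-data generator that
    emulates the statistical structure of a midgut RNA-seq experiment so the
    whole pipeline can be exercised without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
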