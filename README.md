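# midgutatlas

An R package for building a compartmentalized expression atlas of the insect
midgut from a de novo transcriptome, modeled on the anatomy of pentatomid
stink bugs (*Nezara viridula* and relatives): four midgut compartments
M1–M4 along the anterior–posterior axis plus the non-midgut carcass, with
bacterial symbionts resident in M4. It is written for entomologists and
bioinformaticians who have a Trinity-style protein set, replicate TPM
tables, and term annotations, and want the full analysis chain as tested,
reusable functions.

## What it computes

* **Unigene reduction** — longest isoform per Trinity gene, exact-substring
  containment deduplication, and removal of genes with significant
  (e < 10⁻⁵) bacterial/plant best hits (the removed bacterial-like set is
  profiled by per-gene one-way ANOVA before being dropped).
* **Expression atlas** — replicate-mean TPM; presence calls (> 1 TPM,
  strict); the 15-cell compartment-overlap partition; Top-500 groups per
  compartment; sample PCA; per-gene ANOVA on log₂(TPM+1).
* **Fuzzy C-means clustering** (c = 8, fuzzifier m = 1.25) of per-gene
  standardized profiles over M1–M4, keeping genes with membership
  u > 0.6. Memberships follow the standard FCM update
  u_ij ∝ d_ij^(−2/(m−1)) with a monotone objective Σ uᵐ d² and seeded
  restarts.
* **Term enrichment** — for a group of n genes in a universe of N with K
  term-annotated genes and overlap k, the one-sided Fisher p is the
  hypergeometric upper tail P(X ≥ k), computed in log space; terms with
  K < 10 are skipped; Benjamini–Hochberg FDR is applied jointly across all
  tests and rows with FDR < 0.001 reported.
* **Gene-family identification** — cytochrome P450s (forward + reciprocal
  homology at e ≤ 10⁻³ and query coverage > 40%, 150–650 aa, heme-ligand
  motif or external domain table, exact-overlap fragment joining) and
  nutrient transporters (AAAP, APC, NSS, POT, SP, SSS, SWEET: reciprocal
  top-5 family voting, ≥ 20% identity, ≥ 3 Kyte–Doolittle transmembrane
  segments, family length ± 1 SD), iterated until no new members are found.
  The homology engine is local Smith–Waterman (BLOSUM62, gap open 11 /
  extend 1) with a Karlin–Altschul e-value layer; external 12-column hit
  tables are accepted interchangeably.
* **Synthetic data** — a generator that plants Trinity-style catalogs,
  contaminants, eight archetypal expression patterns, marker terms and
  motif/TM-bearing gene families with known truth, so the entire pipeline
  runs and is testable with no sequencing data.

## Worked example

```r
library(midgutatlas)

cfg <- run_config(list(outdir = "demo_run", seed = 1,
                       simulate = list(n_genes = 500)))
res <- run_pipeline(cfg, quiet = TRUE)
str(res$report$counts)
#> $ records_in                 : int 755
#> $ genes                      : int 522
#> $ after_dedup                : int 497
#> $ removed_contained          : int 25
#> $ removed_taxon              : int 53
#> $ unigenes                   : int 444
#> ...
#> $ enriched_rows              : int 8
#> $ family_calls               : int 22
```

755 isoform records collapse to 522 genes; 25 are exact substrings of
longer proteins and are deduplicated; 53 bacterial/plant-like genes are
removed, leaving 444 unigenes. Each fuzzy cluster then recovers the marker
term planted in its archetype:

```r
head(res$enrichment[, c("group", "term_id", "k", "K", "fdr")], 3)
#>                  group term_id  k  K          fdr
#>  cluster1_fuzzycluster  PF9003 18 21 1.849693e-12
#>  cluster2_fuzzycluster  PF9004 20 22 9.056289e-13
#>  cluster2_fuzzycluster  PF9005  8 10 6.036866e-04
```

(k of the K term-annotated genes fall in the cluster; all FDRs are far
below the 0.001 reporting gate.) The family stage recovers every planted
member of the three default families — 8 P450-like, 8 sugar-porter-like and
6 amino-acid-transporter-like genes:

```r
table(res$families$calls$family)
#> AAAP  CYP   SP
#>    6    8    8
```

All outputs (FASTA, TSV tables, gene lists, membership matrix, JSON report)
are written under `cfg$outdir`. A thin CLI wrapper is installed as
`exec/atlas` (`atlas simulate`, `atlas run`).

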