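---
title: "Methods: a compartmentalized expression atlas of the stink bug midgut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a compartmentalized expression atlas of the stink bug midgut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midgutatlas)
```

## The problem

The midgut of pentatomid stink bugs such as *Nezara viridula* is divided into
four morphologically distinct compartments along the anterior-posterior axis
(M1-M4; the microscopic hindgut is pooled with M4 because the two cannot be
dissected apart, and the remaining body is the "carcass"). The M4 compartment
harbors bacterial symbionts. `midgutatlas` implements the analysis chain that
turns a de novo transcriptome of these tissues into an expression atlas:

1. **Unigene reduction** -- one representative protein per Trinity gene
   (longest isoform), exact-substring containment deduplication, and removal
   of bacterial/plant-like contaminant genes.
2. **Expression profiling** -- replicate-averaged TPM, presence calls,
   compartment-overlap (Venn) partitions, Top-N highly expressed groups, PCA
   of samples, and per-gene one-way ANOVA across gut regions.
3. **Fuzzy C-means clustering** of standardized expression profiles along
   the midgut and extraction of high-membership gene groups.
4. **Term enrichment** of all gene groups (clusters and Top-N) by one-sided
   Fisher's exact tests with joint Benjamini-Hochberg FDR control.
5. **Gene-family identification** -- cytochrome P450s and nutrient
   transporters (AAAP, APC, NSS, POT, SP, SSS, SWEET) by reciprocal-homology
   voting with transmembrane-count and family-length filters.

Because raw sequencing data are impractical to carry around, the package
includes a first-class synthetic-data generator whose output exercises every
downstream stage with known planted truth.

## Unigene reduction

Trinity accessions (`TRINITY_DN1000_c115_g1_i1`) are parsed at the gene
("g") level; the longest protein per gene is kept. Ties on length are broken
by the lexicographically smaller isoform identifier -- the upstream assembler
gives no principled ordering, so determinism is the only requirement.
Containment deduplication removes proteins that are exact substrings of
longer surviving proteins (sequence identity 1.0; no near-identity
clustering), scanning in decreasing length order so the result is
independent of input order; identical sequences keep the smaller gene id.
Contaminant filtering discards genes whose best taxon-annotated hit is
bacterial or plant-like with e-value strictly below 1e-05; the removed set
is kept, because the bacterial-like fraction is itself of interest (symbiont
expression concentrates in M4) and is profiled by per-gene ANOVA before
being dropped.

The stage order is fixed: isoform selection, then dedup, then taxon
filtering. Each filter is idempotent.

## Expression quantities

Mean TPM is the arithmetic mean over biological replicates (four by
default). Presence in a tissue means mean TPM **strictly greater than 1**; a
gene at exactly 1 TPM is absent. The overlap partition assigns each gene
present in at least one of M1-M4 to exactly one of the 15 non-empty presence
patterns, so the cells sum to the number of genes detected anywhere.

Top-N groups (default N = 500) rank genes by mean TPM within a tissue; ties
that span the cut are resolved toward lexicographically smaller gene ids,
which makes the group at N a subset of the group at N + 1.

PCA treats (tissue, replicate) columns as samples and genes as variables,
centered and scaled to unit variance with zero-variance genes dropped --
the convention of the standard R PCA toolchain.

Per-gene one-way ANOVA runs on log2(TPM + 1). The pseudocount of 1 is a
choice (zeros are common in TPM tables); the F statistic is the standard
between/within decomposition and is unaffected by shifts. Degenerate genes
with all-identical values report F = 0, p = 1. Significance flags use BH at
0.05 across the tested subset; BH was chosen for consistency with the
enrichment stage.

## Fuzzy C-means

Profiles are standardized per gene (subtract mean, divide by SD) over M1-M4
only -- the clustering describes patterns *along the midgut*, and including
the carcass would let a single non-gut contrast dominate; the tissue set is
an argument if a different view is wanted. Genes with zero variance or
never above 1 TPM in the selected tissues are excluded and reported.

The clusterer is standard FCM with Euclidean distance: memberships
$u_{ij} \propto d_{ij}^{-2/(m-1)}$ normalized per gene, centroids the
$u^m$-weighted means, objective $J = \sum_{ij} u_{ij}^m d_{ij}^2$. An exact
centroid hit receives full membership. The objective is non-increasing every
iteration; convergence is $|\Delta J| < 10^{-8}$ or 300 iterations.
Centroids are initialized from distinct data rows; 20 seeded restarts are
run and the best final objective wins.

Parameter choices:

* **c = 8 clusters** -- the eight archetypal midgut patterns.
* **fuzzifier m = 1.25** -- deliberately small. The retention rule keeps
  only genes with membership strictly above alpha = 0.6, which presumes
  decisive memberships; large m (e.g. the common 2) flattens memberships
  toward 1/c = 0.125 and would empty every group. Both m and alpha are
  configurable.
* Assignments above alpha = 0.6 are necessarily unique (alpha > 0.5);
  membership exactly 0.6 is *not* retained.

## Enrichment

For each (group, term) pair the contingency table is built by exact set
intersection against a fixed gene universe (duplicated annotations count
once), and the one-sided over-representation p-value is the hypergeometric
upper tail $P(X \ge k)$, summed in log space so it is stable down to
~1e-300. Terms annotated to fewer than 10 genes are excluded *before*
testing -- the threshold is read as a bound on the term's size in the
universe (the alternative reading, a bound on the overlap k, is available
via `min_mode = "group"`). BH adjustment is applied jointly across every
surviving test of the run, and rows with FDR < 0.001 are reported.

The default universe is the decontaminated unigene set. In the published
atlas this set contains 25,890 genes, and the package's checks against the
published Top500 contingency rows use exactly that universe size; the raw
p of a row can never exceed its BH-adjusted value, which is what makes
those rows testable without re-running the original annotation.

## Gene-family identification

The homology engine is local Smith-Waterman alignment (BLOSUM62, affine
gaps: a gap of length g costs 11 + g) with a bit-score/e-value layer using
fixed Karlin-Altschul constants (lambda = 0.267, K = 0.041) and
E = m n 2^(-S'), with m, n the pair's sequence lengths. An optional exact
k-mer seeding screen (word size 6) skips alignment of pairs that share no
seed word -- the same pruning idea BLAST uses; the annotation pipelines
enable it, and external 12-column hit tables can be supplied instead. The
alignment scores are verified exhaustively against a brute-force Gotoh
dynamic-programming oracle on small instances in the test suite.

**P450s:** a unigene is a candidate iff a curated reference P450 hits it at
e <= 1e-3 with query coverage > 40%, the reciprocal search back against the
curated set passes the same thresholds, its length is 150-650 residues
(inclusive), and it carries a P450 domain. With no HMM library in-repo, the
domain check defaults to the P450 heme-ligand motif F-x-x-G-x-[RH]-x-C-x-G;
an externally computed per-gene domain table can be supplied instead, so a
real Pfam scan plugs in unchanged. Overlapping candidate fragments are
joined when a suffix of one equals a prefix of another over >= 20 residues
at 100% identity (protein-level; the nucleotide-level behavior of the
original assembly step is not reconstructable); incompatible competing
joins are left unjoined and logged.

**Transporters:** candidates found by the same forward search against pooled
reference panels (two reference species per family) are classified by
reciprocal-hit voting: the top hit's family wins iff (i) it is the top hit,
(ii) at least 4 of the top 5 hits are in that family (or, for families with
fewer than 5 reference members, all members appear in the top 5), and
(iii) the best percent identity to the family is >= 20% ("similarity" is
read as percent identity over the aligned region -- that is what tabular
hit output provides -- and is switchable). Accepted transporters must also
have >= 3 predicted transmembrane segments and a length within one sample
standard deviation of the family's combined min/max (bounds inclusive).

Transmembrane segments are called by Kyte-Doolittle hydropathy: mean
hydropathy over a 19-residue sliding window, maximal runs of windows above
1.6 become segments, and segments separated by fewer than 5 residues merge.
This is a deterministic, self-contained segment caller; agreement with
dedicated topology predictors is not claimed, and both window and threshold
are configurable.

Accepted candidates join the query set and the search iterates (up to 5
rounds) so diverged family members reachable only through an intermediate
are still found; calls are never revoked.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, with
defaults chosen once as plausible study conditions:

* **2000 background genes**, Trinity-style ids; 30% with extra shorter
  isoforms; 5% planted as exact substrings of longer records (so dedup has
  real work); **9% contaminants** (close to the published bacterial-like
  fraction 2512/28402), biased toward M4-type expression as symbiont genes
  are, and marked via a taxon-annotation table with e-values below 1e-05.
* **Eight expression archetypes plus a flat background**: four
  single-compartment peaks, monotone increase and decrease along M1-M4, an
  anterior (M1-M3) and a posterior (M2-M4) block. Default weights are 0.07
  per archetype and 0.44 flat; recovery benchmarks use equal weights over
  the eight archetypes with no flat class. Per-gene abundance is lognormal.
* **Replicate noise is multiplicative lognormal** with mean 1 and
  configurable CV (default 0.2; replicate-level variance is a free choice
  and deliberately configurable). TPM is positive and right-skewed, which
  lognormal noise reproduces with one parameter; `noise_cv = 0` reproduces
  archetype means exactly, which the recovery tests exploit.
* **Planted families** (default: one P450-like and two transporter-like)
  derive members and two-species reference panels from a common family
  ancestor by mutating ~12% of non-template positions, so genuine sequence
  homology -- not just the template -- links members to panels. Hydrophobic
  template stretches use {L, I, V, F, A} and linkers hydrophilic residues,
  making the hydropathy caller decisive. Background genes are scrubbed of
  chance P450 motif matches so the decoy set is clean by construction.
* A term-annotation table plants one marker term per archetype (50%
  prevalence inside the group, 1% outside) among null terms, giving the
  enrichment stage known positives and negatives.

Everything is generated under a single integer seed and is byte-identical
across runs with the same spec.

What the generator does **not** emulate: read-level sampling noise and
mapping ambiguity, assembly fragmentation and chimerism, codon-level or
phylogenetic sequence realism, correlated expression between genes, and
isoform-level quantification. Passing the planted-truth benchmarks
therefore demonstrates the correctness and calibration of the algorithms
under their stated assumptions, not performance on any real transcriptome.

## Problem sizes and numerical choices

The recovery benchmarks run at 2000 genes (clustering), 150 background
genes plus ~22 planted family members with >= 5x decoys (family
annotation, 10 seeds; 20 null seeds), 100 seeded repetitions for the
null-enrichment FDR check, and exhaustive small-instance oracles (all
hypergeometric tables with N <= 60; all alignment pairs in a 50-sequence
fixture of <= 30-residue sequences). These sizes were chosen so the whole
suite completes in a couple of minutes while leaving each check's power
intact.

Strict-versus-inclusive decisions, collected: presence > 1 TPM (strict);
taxon filter e < 1e-05 (strict); homology e <= 1e-3; query coverage > 40%
(strict); membership retention > 0.6 (strict); family length window
inclusive; expression-summary thresholds > 5 and > 50 TPM (strict).
Equal-score ties anywhere are broken lexicographically.

## Known limitations

* The e-value layer uses fixed ungapped Karlin-Altschul constants applied
  to gapped scores and per-pair lengths rather than database length; it is
  calibrated enough to separate homologs from noise at the 1e-3 cutoff used
  here, but its absolute values are not BLAST's.
* The containment step cannot recover whatever non-substring redundancy the
  original clustering tool may have removed under its default word size;
  exact-substring semantics are adopted deliberately.
* The motif-based P450 domain check is a stand-in for an HMM domain scan;
  for real data, supply the external domain table.
* Fragment joining requires exact overlap; sequencing-error-induced
  near-overlaps are not joined.
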