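---
title: "Models and methods behind tcrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdyn)
```

## The analysis problem

`tcrdyn` analyses longitudinal T-cell receptor beta (TCRβ) clonotype
repertoires from sorted T-cell subpopulations — the kind of dataset produced
when patients under two contrasting immune therapies (a one-shot immune
reset, AHSCT, versus continuous natalizumab, NTZ) are sampled before
treatment (t0) and after 24 months (t24), with 4–7 sorted CD4/CD8
naive/memory subpopulations sequenced per patient and timepoint. A *clone*
throughout is a V gene, J gene and CDR3 amino-acid sequence; its abundance
is a read count, normalized to a within-repertoire frequency.

Single summary statistics hide most of the structure of such data, so the
package computes several complementary views: clonal expansion (Hill
evenness profiles), clonal persistence across timepoints, public/private
clone sharing, repertoire architecture (sequence-similarity networks and
k-mer spectra), and annotation against curated CDR3 databases. Each view is
exposed as ordinary functions plus a pipeline (`run_pipeline()`) that writes
plain tables.

## Diversity model

For clone frequencies $f_1,\dots,f_{SR}$ (SR = species richness, the number
of unique clones):

* Shannon entropy $H = -\sum_i f_i \ln f_i$ (natural log — the evenness
  definition exponentiates with $e$, so the base must cancel).
* Shannon evenness $SE = e^{H} / SR \in (0, 1]$: 1 for a perfectly even
  repertoire, near 0 when few clones dominate (a polarized repertoire).
* Hill diversity $^qD = \big(\sum_i f_i^q\big)^{1/(1-q)}$, with
  $^0D = SR$ and the $q\to1$ limit $e^{H}$ taken analytically: values of
  $q$ within $10^{-9}$ of 1 are routed to the closed form rather than
  interpolated, so the profile is exact at the singularity.
* The clonal-expansion (evenness) profile is $^qD/SR$ on a grid of $q$
  from 0 to 10 in steps of 0.2 (51 points, configurable). Its value at
  $q=0$ is identically 1 and it is non-increasing in $q$; the parameter
  $q$ controls how strongly abundant clones are weighted.

Profiles are compared across samples by Pearson correlation of the raw
profile vectors; a log-scale option exists because the choice is not forced
by the definition. A perfectly even repertoire has a constant profile and
hence no defined correlation with anything; such pairs are flagged `NA`
rather than silently dropped, and self-correlations are fixed at 1.

## Persistence, publicity, architecture

*Clonal persistence* between repertoires $A$ and $B$ is
$100\cdot|A\cap B| / \mathrm{mean}(|A|,|B|)$, computed on clone keys only
(no frequency weighting — the measure counts clones; "mean" is the
arithmetic mean). *Public* clones are those present in at least two
repertoires; the sharing unit defaults to the sample, with a patient-level
option since both readings occur in practice. The "highly shared" export
uses a default threshold of at least 11 samples (i.e. more than 10).

The *LD-1 network* of a repertoire takes the top 10,000 CDR3 strings by
aggregated clone frequency (ties broken by count, then lexicographically;
clones sharing a CDR3 but differing in V/J are one node with summed
frequency) and connects two nodes when their Levenshtein distance is
exactly 1. The neighbour search is hash-bucketed rather than all-pairs:
same-length strings are grouped by masking each position in turn
(substitutions), and strings of adjacent lengths are matched through
single-character deletions; strings whose lengths differ by two or more can
never be at distance 1. The search is contractually edge-identical to the
brute-force all-pairs computation, and the test suite enforces this against
`utils::adist` on random fixtures up to 2,000 nodes. Degree distributions
and the percentage of connected (degree ≥ 1) clones, overall and split by
publicity, summarize each network.

The *k-mer profile* decomposes every distinct CDR3 into overlapping
subsequences of length $k = 3$ and normalizes the aggregated occurrence
counts to a frequency distribution. The default counts each distinct CDR3
once (sequence-level counting); weighting by clone frequency is available
as an option since both conventions are defensible. Profiles are aligned on
the union of observed k-mers with explicit zeros before Pearson
correlation.

## Group statistics and clustering

Group comparisons use the Wilcoxon family, disambiguated by design:
unpaired rank-sum for between-treatment contrasts (different patients) and
paired signed-rank for within-patient t0 vs t24 contrasts. P-values are
two-sided, exact by full enumeration when the combined sample size is at
most 12 with no ties, and the normal approximation with tie/continuity
correction otherwise; the method used is recorded in every output row. Raw
p-values are primary (reported with `*` p < 0.05 and `**` p < 0.01);
Benjamini–Hochberg adjusted values are additionally emitted as good
practice. Heatmap-style clustering uses correlation-based distance
($d = 1 - r$) with average linkage by default — the linkage is a documented
package choice, as only the distance is canonical — and Euclidean distance
for degree-distribution matrices.

## The synthetic cohort generator

The generator exists so that every pipeline stage can be tested end to end
with known ground truth. It emulates the study design described above: 7 AHSCT
patients with 4 sorted subpopulations (pooled memory) and 8 NTZ patients
with 7 subpopulations (CM/EM/TEMRA resolved), two timepoints each — 168
samples. Design choices:

* **Frequencies** follow a geometric (exponential-rank) law
  $f_i \propto e^{-a i}$ with polarization $a \ge 0$. This is not a fitted
  biological law; it was chosen for closed-form control of evenness, which
  is the property the analysis actually consumes. $a = 0$ gives a perfectly
  even repertoire, and evenness decreases strictly in $a$.
* **Sampling-free mode** (`read_depth = 0`, the default) assigns the exact
  generative frequencies, with counts a deterministic integer rendering
  (`max(1, round(f * 100 * n))`), so formula-level properties can be
  verified without Monte-Carlo noise. Multinomial read sampling at a
  configurable depth is opt-in; sampled repertoires may lose zero-count
  clones, as real sequencing does.
* **Persistence** is injected structurally: exactly
  `round(persistence_fraction * n_clones)` t0 clone keys are carried to
  t24 (with freshly drawn frequencies), and fresh t24 clones are drawn with
  the t0 keys excluded, so measured persistence equals the injected
  fraction exactly in the sampling-free mode.
* **Public clones** come from a cohort-wide pool allocated to t0 samples
  cyclically (round-robin); injected clones reach t24 only through
  carry-over, keeping the persistence identity intact. Cyclic allocation
  spreads pool usage evenly, so whenever cohort-wide injections are at
  least twice the pool size every pool member lands in at least two
  samples and must be classified public.
* **CDR3s** are random strings anchored `C…F` with uniform interior letters
  and lengths uniform on 8–20, mimicking junction conventions; V/J labels
  are drawn from built-in TRBV/TRBJ gene lists. Collisions are redrawn, so
  clone keys are unique within a repertoire by construction.
* **Seeding** is hierarchical: each sample's stream is derived from the
  master seed and the sample's identity string (`derive_seed()`), so adding
  or removing a sample never changes any other sample's draws, and the
  whole cohort is a pure function of its spec.

Default parameter values are fixed once: `n_clones = 1000` per repertoire
(a desk-scale stand-in for real repertoires, which run an order of
magnitude larger; the full 168-sample default cohort remains comfortable on
a laptop), `polarization = 0.002` (evenness around 0.85, typical of
little-expanded compartments, and mild enough that a 50× sequencing depth
retains essentially every clone — mirroring the clonal-coverage saturation
such studies verify before analysis), `persistence_fraction = 0.2`
(mid-range of the per-subpopulation persistence percentages such cohorts
report, between near-zero naive and ~35% memory values),
`public_pool_size = 500` with `public_injection_rate = 0.02`, and a 50/50
HLA-DRB1*15:01 carrier draw per patient.

What the generator does **not** model: V(D)J recombination statistics,
thymic or antigen-driven selection, subpopulation-specific frequency laws,
sequencing error, or patient-level covariance between subpopulations.
Passing tests on synthetic cohorts therefore certify the *computations*
(formulas, set operations, graph construction, bookkeeping), not any
biological claim about real repertoires.

## Numerical and degenerate-input conventions

* Frequencies must be positive and sum to 1 within `1e-9`; they are always
  recomputed from counts on file ingestion (a single normalization
  authority) and never trusted from a file.
* Gene allele suffixes (`*01`) are stripped for the clone key, because the
  clone definition is gene-level and databases mix conventions; the
  original call is retained alongside.
* Invalid CDR3s (characters outside the 20-letter alphabet, empty strings)
  are dropped at ingestion with a logged count — conservative and visible,
  since no quality rule is canonical.
* Zero-variance inputs to any Pearson correlation yield `NA` flags with
  warnings, never errors; empty publicity classes in connectivity
  percentages behave the same way.
* Database matching is exact string equality after uppercasing; leading
  C / trailing F anchors are *not* trimmed or added, because boundary
  conventions differ across databases and silent editing is worse than a
  documented exact-match contract.
* Top-N and tie-breaking rules, sample orderings and file formats are all
  deterministic, so pipeline runs are byte-reproducible given a seed.

## Problem sizes used in the shipped checks

The package's own test suite runs the full default synthetic design (168
samples of 1,000 clones) end to end twice to verify byte-level
reproducibility, checks network construction against brute-force
Levenshtein on fixtures up to 2,000 CDR3s, and verifies persistence
recovery across 20 multinomial replicates at 50× clone read depth. These
sizes are the package's chosen verification scale; all are configurable
upward through `cohort_spec()` and the pipeline parameters.

## Known limitations

* The loader starts from clone tables; read-level processing, V(D)J
  assembly, UMI handling and nucleotide-level clonotyping are out of scope.
* No rarefaction or coverage-corrected diversity estimators are provided;
  comparisons assume repertoires are analysed at their sequenced depth.
* Database overlap counts are snapshot-dependent by construction; the
  package never fetches databases and reproduces no dated snapshot totals.
* The persistence measure is presence-based; it does not model frequency
  trajectories or clonal lineages across timepoints.
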