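---
title: "Spectral-count differential proteomics: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential proteomics: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcount)
```

## The counting model

Label-free spectral counting assumes that, within one LC-MS/MS run, the
number of peptide-spectrum matches (PSMs) attributed to a protein scales
with its abundance. `spcount` works at the accession level: each PSM row
contributes one count to exactly one accession, with no shared-peptide or
razor-protein apportionment. This is the simplest defensible protein
inference when the upstream search already reports flat accessions; users
whose search engines emit protein groups should collapse them before
import. When several samples are run per condition, counts pool by
summation (`count_spectra()` with a label-to-samples mapping), mirroring
designs where tissues from several animals are pooled into one sample per
condition.

## The Rsc statistic

The fold change between a treatment sample (counts $n_s$, total $t_s$) and
a reference sample ($n_n$, $t_n$) is estimated as

$$R_{sc} = \log_2\frac{n_s + f}{n_n + f} +
  \log_2\frac{t_n - n_n + f}{t_s - n_s + f}.$$

The pseudo-count $f$ (default **1.25**, the conventional value for this
statistic) serves two purposes: it keeps the ratio finite when a protein
has zero counts in one condition — such proteins are retained and handled
by $f$, never special-cased — and it shrinks ratios built on very few
spectra toward zero, which is why a protein observed once in only one
condition is not called differentially expressed. The second log term is a
depth correction: it compares the *rest* of each sample, so unequal total
spectra do not masquerade as fold change. When counts are small relative
to the totals and depth is matched, $R_{sc} \to \log_2(n_s/n_n)$; at
$n_n = 500$, $n_s = 1000$, $t = 10^6$ the statistic is within 0.002 of
$\log_2 2$, which is why the threshold $|R_{sc}| > 1$ operationalizes
"more than a two-fold change".

Classification uses **strict** inequalities (`classify_rsc()`): a value of
exactly 1 is `unchanged`. The reference/treatment orientation is fixed by
the order of the condition labels (reference first); positive values mean
higher expression in the treatment condition. Swapping the conditions
negates every $R_{sc}$ exactly, a property the test suite asserts at
`1e-12`, the float tolerance used throughout.

## NSAF

The normalized spectral abundance factor divides each protein's count by
its sequence length (longer proteins yield more peptides, hence more
spectra) and renormalizes over the whole matrix:
$NSAF_n = (SpC_n/L_n) / \sum_i (SpC_i/L_i)$. Both conditions share one
protein universe — zero-count proteins contribute 0 to the numerator but
remain in the denominator's index — so NSAF vectors from the two
conditions are directly comparable and each sums to 1 (asserted to
`1e-12`). Lengths come from a FASTA (`read_lengths_fasta()`, accession =
first header token by default, configurable regex) or a two-column table;
a missing length is an error naming the accession, never a silent drop.

## Identification sets and enrichment

"Identified in a condition" means spectral count ≥ `min_count` (default
1); `venn_compare()` reports shared/unique counts and percentages of the
union, rounded **half-up** to one decimal, the convention of printed Venn
figures (base R's round-half-to-even would print 6.25% as 6.2%).

Enrichment (`enrich()`) is a local, reproducible stand-in for web-based
annotation tools: one-sided hypergeometric upper tail $P(X \ge k)$ via
`stats::phyper`, with Benjamini–Hochberg adjustment across the reported
categories and a `min_k` reporting floor (default 2). The default
background is the set of identified proteins, not a whole genome — the
natural choice when the question is "which categories are enriched among
the changed proteins, given what this experiment could see"; it is an
argument, not an assumption. An `ease = TRUE` flag discounts one DE
member from the category ($P(X \ge k-1)$), the conservative variant
popularized by DAVID-style tools, for users comparing against such
output. No GO-graph propagation is performed; categories are opaque
labels.

## Wound healing

`healing_percent()` is the closed form
$(area_0 - area_t)/area_0 \times 100$, generalized to any evaluation time
$t$; areas are caller-defined units (ImageJ pixel areas are typical) since
only the ratio matters, and the function is exactly scale-invariant.
Negative values (wound growth) are legal. `summarize_healing()` reports
per-group mean ± SEM ($sd/\sqrt n$) and refuses groups of fewer than two
subjects rather than returning an undefined SEM.

## The synthetic generator

`simulate_spectral_counts()` emulates the statistical skeleton of a
two-condition spectral-counting experiment:

* **Baseline abundances** are log-uniform over 3 orders of magnitude
  (`abundance_decades = 3`). A few-hundred-protein identification list from
  a tissue proteome spans roughly this observable dynamic range; wider
  true ranges exist, but proteins far below one expected spectrum are
  simply never seen.
* **Planted changes**: a `de_fraction` (default 0.1) of proteins has its
  weight multiplied or divided (equal probability) by `fold_change`
  (default 4) in the treatment condition, then both abundance vectors are
  renormalized to sum to 1. Renormalization means the *realized* fold
  change of a planted protein differs slightly from the nominal value —
  exactly as in a real compositional measurement.
* **Counts** are multinomial draws from the condition's abundance vector,
  with the total itself Poisson around `depth` (default 5000, with 500
  proteins approximating an experiment that identifies a few hundred
  proteins from a few thousand spectra). Multinomial-conditioned-on-Poisson
  was chosen over independent Poissons so that true abundances sum exactly
  to 1; by Poissonization the per-protein marginals are Poisson anyway.
* **Determinism**: every draw derives from the config's `seed`; a re-run
  is byte-identical. Passing a previous `truth` table re-draws counts
  under the same ground truth, which is what calibration and power sweeps
  need.

The generator models pure sampling noise only. It does not model peptide
detectability, dynamic-exclusion saturation, run-to-run retention-time
variation, shared peptides, or biological replicate variance — so passing
recovery tests demonstrates that the statistic behaves correctly under
count noise, not that any particular real experiment achieves the same
sensitivity.

`evaluate_recovery()` scores sensitivity (planted proteins recovered with
the correct sign), false-positive rate (null proteins called in either
direction), and sign accuracy among recovered. Where a minimum expected
count filters the scored proteins, the expected count is defined as the
**mean of the two conditions' expectations** (`depth ×` mean abundance) —
symmetric, and equal to either condition's expectation under the null.

## Numerical and testing choices

* Float comparisons use `1e-12` throughout the suite; Rsc is computed from
  natural logarithms with a single division by `log(2)`.
* Degenerate inputs fail loudly: totals smaller than counts, non-positive
  $f$, all-zero conditions, duplicate accessions, and zero initial wound
  areas are errors, never clamped values.
* Output tables sort by decreasing Rsc with accession as the
  deterministic tie-break.
* Monte-Carlo checks use 100 seeds per arm at 500 proteins × depth 5000
  (a few seconds of CPU); sweeps asserting monotone power use 8 seeds per
  grid point at 300 proteins, with medians to damp seed noise.

One calibration finding is worth stating plainly: with a 3-decade
log-uniform abundance range at depth 5000, the *theoretical*
false-positive rate of the $|R_{sc}| > 1$ rule among null proteins with
expected count ≥ 5 is ≈ 0.053 (exact Poisson tail sums; the rate is 0.18
at an expected count of 5 and falls below 0.01 beyond ~25). The
Monte-Carlo estimate in the acceptance suite (≈ 0.055) reflects that
property of the threshold rule itself, not an implementation artifact:
a fixed fold-change cutoff is anti-conservative for proteins near the
detection floor, which is precisely why modern count-based methods add a
significance test on top. The package reports the measured rate honestly
rather than tuning the simulation to flatter it.

## Known limitations

* No significance testing of spectral counts (G-test, beta-binomial,
  QSpec-style models) — the threshold rule is the implemented method, and
  its near-floor false-positive behaviour is documented above.
* No parsing of Mascot DAT, mzIdentML or pepXML; imports are delimited
  tables with a column mapping.
* No protein grouping/parsimony and no FDR filtering of PSMs; the package
  trusts its input identifications.
* Enrichment treats categories as flat labels; hierarchical ontology
  structure is out of scope.
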