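---
title: "Copy-number dosage analysis from low-coverage read depth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number dosage analysis from low-coverage read depth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagescan)
```

dosagescan estimates gene copy numbers from low-coverage whole-genome
sequencing reads mapped to a coding-sequence (CDS) reference, and connects
those estimates to transcript abundance.  It is aimed at non-model
organisms without an assembled genome — herbarium-quality material skimmed
at well below 1x coverage is the typical input — where copy-number variants
of, say, a metabolic gene family are the biological signal of interest.
This vignette documents the statistical model, every tunable parameter
that matters, the synthetic-data generator used for verification, and the
numerical choices behind the implementation.

## The binomial read-count model

Assume each of the $N$ sequenced reads starts at a uniformly random
position in the genome of size $G$.  The count $c_i$ of reads landing in a
single-copy gene of length $L_i$ is then binomial with $N$ trials and
success probability

$$P_i = L_i / G, \qquad E(c_i) = N L_i / G.$$

Real libraries are not uniform: PCR during library preparation makes depth
depend on the GC content $x_i$ of the target, and the strength of this
bias varies between library batches.  dosagescan therefore replaces the
constant rate $1/G$ with a per-sample linear rate in GC,

$$c_i / L_i = a + b\,x_i, \qquad
  P_i = L_i\,(a + b\,x_i) / N, \qquad E(c_i) = L_i\,(a + b\,x_i),$$

estimated from that sample's own counts.  Setting $b = 0$, $a = N/G$
recovers the uniform model exactly (`expected_count()` asserts this
reduction in the tests).  Note $P_i$ no longer involves $G$: samples
without a genome-size measurement can still be analysed, and copy numbers
are expressed per haploid chromosome set because the calibration is
relative to the single-copy mode of the sample itself.

The copy-number estimate for any gene is the observed count relative to
its single-copy expectation,

$$\hat k_i = c_i / E(c_i).$$

## Estimating the GC coefficients

`fit_gc_ensemble()` estimates $(a, b)$ per sample as follows.

1. **Enrichment for single-copy genes** (`filter_candidate_single_copy()`):
   keep genes longer than 700 bp (more reads, more stable rates), with at
   least one read, and with length-normalized count at most 1.5 times the
   median length-normalized count over genes with any reads.  The upper
   cut removes most duplicated genes; the filter operates on the
   length-normalized scale so gene length does not leak into it.
2. **Class-balanced resampling**: the GC range 0.38–0.78 (fraction scale)
   is split into nine equal classes, half-open $[lo, hi)$ except the last.
   Each repeat draws 60 genes per class *without replacement* (a class
   with fewer contributes all its genes; an empty class is skipped, each
   with one warning), pools them (at most $9 \times 60 = 540$ genes), and
   fits ordinary least squares of $c_i/L_i$ on $x_i$.  Balancing stops the
   unimodal GC distribution of real CDS sets from concentrating leverage
   in mid-GC genes; sampling without replacement avoids duplicated points
   distorting OLS leverage.
3. The default 100 repeats give a non-parametric picture of coefficient
   variability; downstream calls are made once per repeat, and summaries
   report the min/median/max across repeats.

Defaults (`n_repeats = 100`, `genes_per_class = 60`, range 0.38–0.78, nine
classes, length cut 700 bp, enrichment cut 1.5, minimum pool 200 genes)
are the operating point of the protocol this package implements; all are
arguments.  One caveat worth knowing: because every repeat draws at most
540 genes, the *spread* of the resampled coefficients reflects the
sampling variability of a 540-gene fit, not of the full pool — it does not
shrink as the pool grows (with a pool of exactly 540 it would collapse to
zero).  What improves with pool size is the accuracy of the ensemble
*median*, which the tests verify to 2% on a 20,000-gene simulation.

## Classification and integer copy numbers

For each ensemble member, each gene gets a two-sided binomial confidence
interval on its count under the single-copy hypothesis, at family-wise
confidence 0.99 Bonferroni-corrected over the $M$ genes with a usable rate
in that sample: per-gene level $\alpha = 0.01 / M$, split equally per
tail.  Bounds use the standard quantile convention (smallest integer $q$
with $\mathrm{CDF}(q) \ge \alpha/2$, resp. $\ge 1 - \alpha/2$); the
interval is inclusive.  `qbinom()` is numerically stable across the
extreme-$N$, tiny-$P$ regime of whole-genome libraries, which the tests
check against exhaustive CDF summation.

The label rule table, in order:

| condition                          | label |
|------------------------------------|-------|
| lower bound $= 0$                  | `excluded_ci_spans_zero` (absence undecidable) |
| $c_i = 0$                          | `absent` |
| $0 < c_i <$ lower bound            | `below_ci_removed` (copy number not estimable) |
| within bounds (inclusive)          | `single` |
| $c_i >$ upper bound                | `duplicated` |

Exclusion wins over everything else: when the interval reaches zero
(expected count below roughly 11.5 at $\alpha/2 = 10^{-5}$), absence
cannot be distinguished from sampling noise, so the gene does not enter
the analysed denominator.  Summaries report percentages of
single/duplicated/absent over the analysed genes only.

Integer copy numbers for duplicated genes are `ceiling(k)` by default —
partial duplications inflate counts by a fraction of a copy, so rounding
up acknowledges at least that many complete copies — with a
`rounding = "nearest"` switch.  For *recovery* of a true integer copy
number the nearest-integer rule is the right tool: $\hat k_i$ is unbiased
around the true $k$, so the ceiling of it lands on $k+1$ for about half
of the draws regardless of coverage, whereas nearest-integer recovery
improves without bound as coverage grows (the SD of $\hat k_i$ is
$\sqrt{k/E(c_i)}$).  The package's recovery tests use
`rounding = "nearest"` with single-copy expectations of roughly 200–400
counts, where 95%+ exact recovery for $k = 2..8$ is attainable; at an
expectation of 50 the $k = 8$ class alone would sit near 79% even with
nearest rounding.

Per-gene consensus across the ensemble is the majority label (ties broken
by a fixed preference order: single, duplicated, absent, removed,
excluded) with the median $\hat k_i$; per-member calls are retained in the
output for audit.

## Theoretical coverage

`theoretical_coverage()` reports
$(\text{read pairs} \times 2 \times \text{read length}) / (2 \times
\text{2Cx genome size in Gb} \times 10^9)$, to two decimals, with a 2.2 Gb
default where the genome size is unknown.  The tests pin this arithmetic
to published accession-level values for 100 and 150 bp libraries.

## The synthetic-data generator

Every stage is verified against `simulate_*()` functions that generate
data *from the model the analysis assumes*, with known ground truth:

- `simulate_reference()`: log-normal gene lengths (median 1.5 kb, floor
  150 bp), Beta-distributed GC on [0.30, 0.85], and integer copies drawn
  from a spectrum defaulting to 86% single, 13.3% duplicated with a
  decaying tail over 2–8, 0.7% absent — the background composition a
  genome scan of a wild diploid grass typically reports.
- `simulate_counts()`: $c_i \sim \mathrm{Binomial}(N, k_i P_i)$ — the
  stated sampling distribution, not a Poisson approximation.  Defaults
  $N = 2 \times 10^6$, $(a, b) = (0.008, 0.005)$ give the few-to-tens of
  reads per single-copy gene of a sub-1x skim.
- `simulate_snp_sites()`: a gene in $k$ copies in a diploid has $2k$
  alleles; each site carries its variant on $m$ alleles, $m$ uniform on
  $1..k$, so genomic variant frequencies concentrate on $m/(2k)$
  (0.125, 0.25, 0.375, 0.5 for $k = 4$).  Transcriptome depths use the
  summed expression weights of the variant-bearing alleles, so unequal
  per-copy expression decouples the two frequencies.
- `simulate_tree_and_traits()`: pure-birth trees; copy numbers from
  thresholding a unit-rate Brownian trait into 1..5; log abundance
  $= \beta \times \text{copies} + $ Brownian noise of rate $\sigma^2$.
- `simulate_qpcr()`: Ct is where $q E^{C_t}$ crosses a fluorescence
  threshold *common to all amplicons* ($C_t = (c_0 \log 2 - \log q)/\log
  E$, $c_0$ the Ct of unit template at perfect doubling).  This keeps the
  two defining identities consistent: one doubling at $E = 2$ shifts Ct
  by exactly one cycle, and efficiency-corrected back-calculation
  ($E^{-C_t}$) inverts the generator exactly at zero noise.  A
  per-amplicon threshold would break the latter whenever efficiencies
  differ.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mappability variation and multi-mapping
ambiguity, sequencing error, non-linear GC bias, partial (sub-gene)
duplications, retroposed exon-only copies, organellar contamination, and
correlated errors between genome and transcriptome libraries.  The tests
demonstrate that the estimators recover the truth *of the assumed model*;
accuracy on real libraries rests on the adequacy of the linear GC-binomial
approximation, which is why the qPCR validation arithmetic is part of the
package.

## Allele-dosage (ASE) analysis

`minor_frequencies()` defines the minor variant of each biallelic site on
the *transcriptome* depths (ties broken to the lexicographically smaller
base, deterministically), and computes its frequency in both data sets;
consequently $f_T \le 0.5$ always, while $f_G$ of that base may exceed
0.5.  One bias is inherent to the definition: at sites whose true
frequency is 0.5, taking the transcriptome-minor side folds the sampling
distribution, pulling the mean down by about
$\mathrm{sd} \times \sqrt{2/\pi}$; the tests account for it at that class.
`ase_correlation()` is OLS of $f_T$ on $f_G$ with the fit's $R^2$ and the
slope's t-test; under equal per-copy expression the slope tends to 1 with
depth.  OLS $R^2$ was chosen as the correlation measure to match a
regression-line presentation of such data.  Sites with zero depth on
either side are dropped and counted; polyploid samples should be excluded
by the caller, as reliable per-site frequencies need coverage
proportional to the allele count.

## qPCR relative quantification

`filter_efficiency()` retains amplification efficiencies in [1.85, 2.1]
(bounds inclusive; efficiencies above 2.2 trigger a unit hint, since
percentage-scale inputs are a common mistake).  `pfaffl_relative_copy()`
computes per-amplicon quantities $Q = E^{-\bar{C_t}}$ from
replicate-averaged Ct, and the target's copy number relative to the mean
quantity of the reference primer pairs, with SEs from the replicate Ct
spread by the first-order delta method.  With all efficiencies at 2 this
is exactly $2^{\Delta C_t}$.  `qpcr_relative_copies()` optionally
renormalizes so the reference gene is exactly 1 — both that scaling and
the raw one are defensible presentations, so it is a switch.

## Phylogenetic regression

Tips of a gene-family tree are not independent observations; shared
branches induce correlated trait deviations.  `pgls_fit()` implements
generalized least squares with the Brownian tip covariance
$C_{ij} = $ shared root-to-MRCA path length (built in
`brownian_covariance()` from node depths; ultrametricity not required;
pure star trees are accepted as the rotation-invariant diagonal case):

$$\hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y,\quad
  \hat\sigma^2 = \frac{r^\top C^{-1} r}{n-2},$$

with a two-sided t-test on the slope at $n - 2$ df.  Computation goes
through the Cholesky whitening transform (identical algebra, better
conditioning); a singular $C$ falls back to a pseudo-inverse with a
warning.  Two identities pin the implementation: $C = I$ reproduces OLS to
machine precision, and rescaling $C$ by any positive scalar leaves the
slope and p-value unchanged ($\hat\sigma^2$ absorbs the scale).  The test
suite additionally checks a five-tip instance against textbook
matrix-inverse algebra and cross-checks slope, SE and p-value against an
independent GLS implementation (`nlme::gls` with a Brownian correlation).

Choices made where the design was genuinely open:

- **Zero abundances**: abundances are transformed as
  $\log_{10}(\mathrm{RPKM} + 1)$.  Observed abundance ranges include 0,
  for which a bare log is undefined; the unit offset anchors 0 at 0 and
  is conventional for RPKM-scale data.
- **Predictor**: the consensus integer copy number (`k_rounded`), not the
  raw $\hat k$ — integer copy classes are what the dosage hypothesis is
  about; absent genes enter with $k = 0$ and their recorded abundance.
- **Multiple trees**: when a family supplies several trees (e.g. posterior
  samples), the first is the primary analysis and the per-tree p-value
  distribution is reported unaggregated, as a robustness readout.
- **No branch-length transforms**: pure Brownian covariance, no Pagel's
  lambda or OU — the model is fixed, not selected.

`run_family_scan()` Bonferroni-adjusts over the number of *testable*
families; families without copy-number variation are reported as
untestable rather than silently dropped.

## Problem sizes and tolerances in the verification suite

The package's own checks run at sizes chosen to make Monte-Carlo noise
small relative to the asserted tolerances while keeping the suite quick:
GC-coefficient recovery on 5,000 genes (5% tolerance) and 20,000 genes
(2%); copy-number recovery on 700 duplicated genes across $k = 2..8$ at
single-copy expectations of 200–400 counts (95% exact recovery,
nearest-integer rounding); family-wise CI coverage on 1,000 replicate
genomes of 500 single-copy genes (99% of genomes fully covered); PGLS
slope recovery over 200 Brownian replicates at $n = 30$ (3 Monte-Carlo
SEs); allele-dosage concentration at depth 500.  Each stochastic check
fixes its seed.

## Known limitations

- The GC model is linear; strongly non-linear bias (very low or high GC)
  is out of scope, as are mappability corrections.
- No positional information is used: no segmentation, breakpoints, or
  sub-gene partial-duplication inference — partial copies surface only as
  fractional $\hat k$.
- The caller assumes counts of *uniquely assigned* primary alignments;
  collapsing of near-identical paralogues must be handled upstream in the
  reference construction.
- PGLS treats the tree as known; topological uncertainty is only probed
  by the multi-tree robustness mode, not integrated over.
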