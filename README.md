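# dosagescan

Gene copy-number estimation from low-coverage whole-genome sequencing, and
the downstream dosage analyses that connect copy number to transcript
abundance.

The package is aimed at groups working on non-model organisms without an
assembled reference genome — for example, population samples or
herbarium material skimmed at well below 1x coverage — who want to know
which genes are duplicated or lost in which accessions, whether the extra
copies are transcribed, and whether copy-number changes track expression
changes across a phylogeny.

## The model

Reads are mapped to a CDS reference and counted per gene.  Under uniform
sampling the count of a single-copy gene of length *L*ᵢ is binomial,
`cᵢ ~ Binomial(N, Pᵢ)` with `Pᵢ = Lᵢ/G` (library size *N*, genome size
*G*).  Because PCR-based library preparation makes depth depend on GC
content, the constant rate is replaced per sample by a linear GC rate:

    cᵢ/Lᵢ = a + b·xᵢ        Pᵢ = Lᵢ(a + b·xᵢ)/N        E(cᵢ) = Lᵢ(a + b·xᵢ)

with (a, b) estimated from the sample's own counts by class-balanced
resampling over nine GC classes (60 genes per class, 100 repeats, after
enriching for putative single-copy genes).  Each gene then gets a
Bonferroni-corrected 99% binomial confidence interval on its count under
the single-copy hypothesis: counts above the interval are duplicated
(copy number `kᵢ = cᵢ/E(cᵢ)`), counts inside are single copy, zero counts
with an interval excluding zero are absent, and genes whose interval
reaches zero are excluded as undecidable.

Companion modules: allele-dosage analysis of per-SNP minor-variant
frequencies in genome versus transcriptome read depths; Pfaffl
efficiency-corrected qPCR relative quantification for independent
validation; and phylogenetic generalized least squares (Brownian
covariance, implemented from matrix first principles) to test for
correlated evolution of copy number and log₁₀ transcript abundance.
A synthetic-data generator with known ground truth backs every stage's
tests.

## Worked example

Simulate a genome scan with known truth, fit the GC model, and call copy
numbers:

```r
library(dosagescan)

cfg    <- simulation_config(n_genes = 3000L, seed = 42L, library_size = 4e6)
sim    <- simulate_reference(cfg)
counts <- simulate_counts(sim$genes, sim$truth, N = cfg$library_size,
                          a = cfg$a, b = cfg$b, seed = 43L, sample_id = "ACC1")

ens <- fit_gc_ensemble(sim$genes, counts, n_repeats = 100L, seed = 44L)
ens
#> gc_fit_ensemble: 100 fits; median a = 0.008412 [0.00745, 0.009469], median b = 0.003986 [0.002005, 0.005536]

calls <- call_sample(sim$genes, counts, ens, rounding = "nearest")
calls
#> cnv_calls: ACC1 - 100 ensemble member(s), 3000 genes
#> call_summary: ACC1 - 1973.5 genes analysed
#>   single:     91.9 (91.5-92.3) %
#>   duplicated: 7.4 (7.0-7.8) %
#>   absent:     0.7 (0.7-0.7) %
```

The ensemble medians sit on the generating coefficients (a = 0.008,
b = 0.005), and the summary gives the background composition of the
simulated genome — percentages of analysed genes called single copy,
duplicated, and absent, with the min–max across the 100 GC-fit repeats in
parentheses.  About a third of genes are excluded at this shallow
coverage because their confidence interval reaches zero.  For the genes
called duplicated, comparing integer estimates with the truth:

```r
dup <- subset(calls$consensus, label == "duplicated")
table(true = sim$truth$true_copy[dup$gene_id], called = dup$k_rounded)
#>     called
#> true  2  3  4  5  6  7  9
#>    2 50 16  0  0  0  0  0
#>    3  2 39  5  0  0  0  0
#>    4  0  2 17  3  0  0  0
#>    5  0  0  1  5  2  0  0
#>    ...
```

At this sub-1x-like depth (16–35 expected reads per single-copy gene)
duplications are detected reliably but the integer copy number is off by
one for roughly a quarter of them — the honest operating regime of
low-coverage scans; at expected counts of 200+, exact recovery exceeds
95% (see the test suite).  Theoretical coverage bookkeeping:

```r
theoretical_coverage(18899157, 100, 1.88)
#> [1] 1.01
```

A thin command-line front end over the same functions ships in
`inst/cli/dosagescan.R` (subcommands `simulate`, `gc-fit`, `call`,
`coverage`, `ase`, `pgls`, `qpcr`).

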