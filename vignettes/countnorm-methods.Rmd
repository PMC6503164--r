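---
title: "Normalization factors and their evaluation: methods behind countnorm"
author: "countnorm developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization factors and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countnorm)
```

## The problem

A raw genes-by-samples expression matrix confounds biology with technical
scale: two samples sequenced to different depths differ in every count even
when no gene changed. Global normalization assumes this nuisance is a single
multiplicative factor per sample, and rescales column $j$ by a factor
$f_j > 0$. Two families of estimators exist. *Control-based* methods assume
the summed expression of a pre-specified gene group (housekeeping genes,
ERCC spike-ins) is constant across samples. *Average-bulk* methods assume
most genes are not differentially expressed, and estimate scale from the
bulk of the distribution (median-of-ratios, upper quartile, trimmed mean of
M-values). Single-cell matrices add a complication: a large share of
entries are zero, and several classical estimators are undefined or badly
biased unless zeros are set aside.

countnorm computes factors for eleven methods under one convention, and —
because no method is best on all data — evaluates them against each other
with metrics that do not presuppose any one method's assumptions.

## Factor conventions

All methods are expressed on a counts-per-million-like scale and then
standardized:

* Library-size methods: $f_j = 10^6 / N_j$, where $N_j$ sums nuclear genes
  (NR), nuclear + mitochondrial (CR), those plus spike-ins (TC), or is the
  externally supplied total aligned read count (TN).
* Control-set methods (HG7, ERCC, GAPDH, TU): $f_j = 10^6 / N^*_j$ with the
  pseudo library size $N^*_j$ summed over the control genes.
* edgeR-style scaled methods (RLE, UQ, TMM): a scaling $s_j$ adjusts the NR
  library size, $f_j = 10^6 / (N_j s_j)$. Returning $s_j$ alone as a global
  factor is a documented misuse; the conversion is always applied here.
* Every factor vector is finally divided by its geometric mean
  (`standardize_geomean()`), so only relative scale survives. This is why
  DESeq (factor $1/N^*_j$) and RLE (factor $10^6/N^*_j$) coincide after
  standardization — they share the same median-of-ratios pseudo size — and
  the package reports them as the single method `DESeq(RLE)`.

"Ignore zeros" is applied uniformly: every per-gene or per-sample statistic
(geometric-mean references, ratio medians, quantiles, M/A values, log-CVs,
RLE values) is computed over strictly positive entries only. Zeros are
data, not missingness; they simply carry no information about relative
scale.

Numerical conventions that downstream values depend on: the third quartile
uses type-7 linear interpolation (UQ and the TMM reference rule depend on
it); TMM trims the extreme `trim_M = 0.3` and `trim_A = 0.05` fractions on
both ends by average rank, with ties resolved identically under gene
permutation; the TMM reference is the sample whose Q75 of positive relative
counts is closest to the mean of those Q75s, ties to the lowest index;
edgeR's internal rescaling of $s_j$ to unit product is skipped because the
final geometric-mean standardization makes it a no-op.

## Ubiquitous genes and TU

The Total Ubiquitous method sums a data-driven gene set chosen to be
comparably expressed everywhere. Per sample, genes with zero counts are
excluded, the remaining $k$ genes are ranked ascending (ties broken by gene
id so results are reproducible), and ranks in
$(\lfloor \text{lower} \cdot k \rfloor, \lfloor \text{upper} \cdot k \rfloor]$
are kept — an integer-only boundary rule that reduces to "keep all" at
$(0, 1]$. A gene is *ubiquitous* if it appears in at least
$\lceil \text{occurrence} \cdot n \rceil$ of the $n$ trimmed sets;
occurrence rate 1 is the strict intersection, and relaxed rates keep the
set usable on large sparse single-cell matrices where the intersection is
tiny or empty. Ubiquitous genes are always derived from the raw matrix and
one set is reused everywhere (TU factors, mSCC) so methods are compared on
identical footing.

The three trimming parameters are chosen by exhaustive grid search
(`tu_search()`) maximizing AUCVC. The presets mirror the two data regimes:
single-cell (occurrence 0.2–0.6 by 0.1, lower 5–40%, upper 60–95% by 5%,
more than 100 ubiquitous genes required — 320 combinations) and bulk
(occurrence fixed at 1, more than 1000 genes). The size constraint is
strict ("more than"); combinations failing it are recorded in the trace
with a reason rather than silently dropped. Ties on AUCVC prefer the
larger ubiquitous set (more genes, more stable sum), then the
lexicographically smallest parameter triple, making the search fully
deterministic. The min–max CV normalization is re-derived per combination,
since each TU normalization changes the CV vector it is scored on.

## Evaluation metrics

**AUCVC.** A gene is "uniform" when its coefficient of variation falls at
or below a cutoff. The raw CV (`cv_raw()`) uses all values including
zeros; the CV actually wired into curves (`cv_log2()`) is the
zero-ignoring dispersion of $\log_2$ expression over its mean, defined only
when a gene has at least two positive values and a positive log-mean
(excluded and logged otherwise — exclusions are rare after
$10^6$-scale normalization since typical values are far above 1). Because
single-cell CVs span a huge dynamic range, no single cutoff is defensible;
instead CVs are min–max normalized to $[0,1]$ and the count of uniform
genes is traced over the full cutoff grid $t/G,\ t = 1..G$ (default
$G = 1000$). AUCVC is the normalized area
$\sum_t \mathrm{counts}_t / (G \cdot n_\mathrm{eligible})$ — the mean
uniform fraction over the grid, in $[0,1]$, higher is better. The
integration rule (even-grid Riemann sum) is the one genuinely open reading
in this design; it is isolated in `aucvc()` and recorded in output
headers. Only genes with a non-zero ratio at or above the evaluation
cutoff enter; positive factors preserve zero patterns, so all methods are
scored on the identical eligible set.

**mSCC.** If normalization succeeded and most genes are independent of
each other, the expression profiles of random ubiquitous gene pairs should
be uncorrelated; residual depth signal correlates everything with
everything. `mscc()` samples up to $10^6$ distinct unordered pairs with a
seeded generator (all pairs when fewer exist), computes Spearman's rank
correlation per pair across samples, and reports the median — nearer 0 is
better. Pairs involving a constant profile are dropped with a logged
count. Sampling is without replacement via index unranking, so a fixed
seed is bit-reproducible.

**RLE_MED / RLE_IQR.** Relative log expression is
$\mathrm{RLE}_{ij} = \log x_{ij} - \mathrm{median}_j(\log x_{i\cdot})$ over
positive entries, natural log. RLE_MED is the mean squared per-sample
median (systematic shift); RLE_IQR is the variance of the per-sample IQR
(spread instability). Both are exactly 0 when all columns are identical.

**Consistency of metrics.** A method that is best by one metric should be
best by the others; disagreement is itself diagnostic. Mode 3 ranks
methods by AUCVC (descending) and mSCC (signed, ascending), splits each
score vector into three tiers by one-dimensional average-linkage
clustering (mirroring a three-group presentation), and flags methods whose
AUCVC and mSCC tiers disagree. Factor vectors themselves are compared by
hierarchical clustering with $1 - \mathrm{SCC}$ distances
(`cluster_factors()`), exportable as Newick.

## The three modes

1. **normalize**: TU search, standardized factors, normalized matrix.
2. **evaluate (simple)**: AUCVC over a non-zero-ratio cutoff grid for HG7,
   GAPDH, ERCC (when spike-ins exist), TN (when totals are supplied), TC,
   CR, NR, DESeq(RLE), UQ, TMM and the raw-data baseline None; best =
   highest mean AUCVC (the source description is self-contradictory about
   TN's membership here; this package includes TN whenever its input
   exists and always reserves TU for modes 1 and 3). Failing methods are
   reported "unavailable", never fatal — e.g. GAPDH on single-cell data
   with zero counts in some cell.
3. **evaluate (complete)**: adds TU (a fresh search per cutoff), mSCC on
   the shared raw-matrix ubiquitous set (taken from the first cutoff's
   optimal parameters), RLE_MED/RLE_IQR, rankings and the consistency
   report.

All modes are deterministic given (matrix, annotation, config, seed).

## The synthetic world

`simulate_counts()` generates matrices with known ground truth: log-uniform
true depths $d_j \in [0.25, 4]$ (16-fold depth variation), negative-binomial
counts with mean $\mu_i e_{ij} d_j$, a 10% minority of genes with two-group
fold changes of $2$–$4\times$, mean-dependent dropout
$p = 0.3\, e^{-\mu/5}$, spike-in rows on a fixed geometric concentration
ladder scaled by an *independent* per-sample spike depth (mimicking
fixed-volume ERCC addition, so spike-in and cellular scale can disagree, as
they do conceptually), low-dispersion housekeeping rows named after the
seven HG7 genes so control-set methods resolve, and total read counts with
a simulated unassigned remainder.

Expression is deliberately **bimodal**: 57% of ordinary genes are "off"
(mean 0.001, essentially never observed) and the expressed remainder is
lognormal$(\log 100, 1.0)$ with dispersion 0.25. This is the standard
picture of a single cell population — roughly half the annotated genome
undetected, detected genes at substantial read counts — and it is also a
mathematical necessity for a coherent stated world: a unimodal low-mean
model can reach a 40–80% zero fraction only by putting most genes at
borderline counts, where the conditional-on-positive inflation of small
counts biases every zero-ignoring ratio statistic by far more than the
depth-recovery tolerances the generator is meant to support. With the
bimodal defaults the single-cell preset sits near 56% zeros and
median-of-ratios recovers standardized true factors to a few percent.

What a green simulation test does *not* establish: the generator has no
gene-length or GC effects, no UMI structure, no cell-cycle or
subpopulation covariance between genes (genes are independent given depth),
and its detection rates are nearly binary (expressed genes are seen almost
everywhere, off genes almost nowhere), so the non-zero-ratio cutoff grid
discriminates less than on real data. Conclusions about method rankings on
real matrices must come from running the evaluation on those matrices —
which is the point of the package.

## Degenerate inputs and edge policies

All-zero samples give empty trimmed sets (warning); an empty ubiquitous
set is an error for `tu_factors()` but a recorded skip inside the search;
a control set with a zero sum in any sample names the sample and fails
that method only; all-identical CVs normalize to all zeros (logged);
constant gene profiles drop out of mSCC; constant factor vectors are
excluded from clustering with a warning. Matrices may contain non-integer
estimated counts — nothing downstream requires integrality. Genes-as-rows
orientation is assumed everywhere; a `--transpose` flag covers the other
convention at the CLI.

## Known limitations

Methods requiring external programs or per-gene factor matrices (network-
centrality and evolution-strategy scalings, SCnorm-style per-gene factors)
are out of scope by design: the package's contract is one global factor
per sample. mSCC on heavily zero-inflated data retains a positive bias
away from 0 even under good normalization (tied zero ranks correlate);
compare methods by relative mSCC, not by its absolute distance from zero.
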