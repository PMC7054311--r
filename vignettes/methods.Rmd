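---
title: "Methods: from paired ethanol microarrays to a TF-target network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from paired ethanol microarrays to a TF-target network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etohnet)
```

This vignette is the package's own account of its statistical machinery:
the models each stage fits, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices made where the published analysis left the design
open.

## The differential-expression model

The input is a probe-by-sample matrix of positive, MAS5-style linear
signals from a paired design: each of `b` experiment batches contributes
one control and one ethanol-treated sample (the emulated study has
`b = 6`, i.e. 12 arrays). Three stages are applied:

**Detection filter.** A probe is analysed only when its fraction of
present calls is at least 0.50 within the controls *or* within the
ethanol samples. When no detection calls accompany the matrix, a
surrogate is used: a probe counts as present in a sample when its signal
exceeds that array's 20th-percentile signal. The surrogate preserves the
filter's contract (a per-array presence call feeding a per-treatment
fraction rule); the floor quantile is a tuning parameter
(`floor_quantile`) because MAS5 detection p-values themselves are out of
scope.

**Treatment test.** Signals are log2-transformed and the additive
two-factor model `log2(signal) ~ treatment + batch` is fitted per probe.
With one observation per treatment-by-batch cell this is the randomized
complete block ANOVA; its treatment F statistic on (1, b−1) degrees of
freedom equals the square of the paired t statistic, an identity the
test suite asserts to 1e-10. The implementation evaluates the closed
form over the whole matrix at once, computing residuals directly
(never as a difference of sums of squares, which cancels catastrophically
when the fit is near-perfect); `stats::aov` is the cross-check oracle in
the tests. Treating batch as a fixed additive block rather than a REML
random effect is exact for this balanced design and avoids estimating a
variance component from 6 levels.

**Selection.** Fold change is computed on the *linear* scale,
`r = mean(ethanol) / mean(control)`, reported in the signed-ratio
convention (`r` if `r ≥ 1`, else `−1/r`; no values inside (−1, 1)).
Storey q-values estimate the null proportion π0 on the λ grid 0.05,
0.10, …, 0.95 with the smoother method (a df-3 smoothing spline through
π0(λ), read off at λ = 0.95 and clamped to (0, 1]); with π0 = 1 the
q-values reduce *exactly* to Benjamini–Hochberg, which the suite checks
on random vectors. A gene is dysregulated iff |FC| ≥ 1.25 **and**
q ≤ 0.15 **and** p < 0.03 — inclusive at 1.25 and 0.15, strict at 0.03,
exactly as the thresholds are printed in the source analysis. Probes are
selected first, then collapsed to genes (smallest p wins; ties broken by
larger |FC|, then probe id), matching the narrated ordering
selected → mapped → genes.

## Promoter scanning with exact p-values

Promoters are the 2 kb windows upstream of each TSS (strand-aware;
windows clipped at contig edges are kept and flagged). Given a PWM count
matrix, the scoring model is the log-likelihood ratio

```
s(i, a) = log2( (c(i,a) + κ·b(a)) / (Σ(i) + κ) ) − log2 b(a)
```

with pseudocount κ = 0.1 distributed by the background frequencies
`b(a)`. Window scores are sums of `s(i, a)` over positions; every window
is scored on the forward strand and against the reverse-complemented
matrix.

**Discretization and the DP null.** Scores are rounded entrywise to
integer multiples of a granularity `g` (default 0.01 bits per bin). The
null distribution of the integer window score under the 0-order
background is computed exactly by dynamic programming — position-wise
convolution of the four-point column distributions — and the reported
p-value of a window is the survival function at its integer score. The
test suite verifies the DP against exhaustive enumeration over all `4^w`
words for widths up to 8. Because the scanner scores windows with the
*same* discretized matrix the DP convolves, p-values are exact for the
scores actually used; discretization only perturbs a window's score by
at most `w·g/2`, so score *orderings* between windows closer than `w·g`
may differ across granularities (the attainable form of the
refinement-stability property, and what the suite checks).

**Strands.** Scoring a window with the reverse-complemented matrix
equals scoring the window's reverse complement with the forward matrix,
so one null distribution prices hits on both strands. This convention
makes reverse-complement symmetry exact — scanning `revcomp(S)` forward
is identical, hit for hit, to scanning `S` on the minus strand — even
when the background is strand-asymmetric.

**Policies.** Windows containing N are skipped (never scored with N
treated as background, which would inflate masked sequence). The default
background is estimated from the scanned promoter set itself (0-order);
a uniform option exists. The occurrence threshold defaults to
α = 1e-4 — the conventional default of this scanner family; the source
analysis prints no threshold, and the per-TF genomic target count K
depends directly on it, so it is prominently configurable. A gene is a
predicted target when it has ≥ 1 occurrence at p ≤ α; no per-promoter
multiple-testing correction is applied, because targets are defined by
occurrence.

## Enrichment, overlaps, and the network

For each TF the upper-tail hypergeometric probability
`P(X ≥ k | N, K, n)` is computed through `phyper` (log-space in the
tail), with an `lchoose`-based brute-force sum as the independent test
oracle over the complete grid N ≤ 60. The universe N is the set of genes
with a scannable promoter — not the whole annotation — because K and k
are only observable there; since p-values depend on this choice, every
run summary logs N. Exports round p and −log10 p to 4 decimals (the
published table's convention, satisfying `round(10^(−x), 4) = p`) while
retaining full-precision companion columns.

The network draws an edge tf → gene iff the TF is dysregulated and
PWM-backed, the gene is dysregulated, and the gene is among the TF's
predicted targets; self-edges (a TF hitting its own promoter) are kept
and flagged. The summary triple (edges, TFs with edges, distinct
targets) is recounted from the exported edge list in the tests, and the
in-degree profile exposes how many targets are shared by multiple TFs.

## Comparative-CT quantification

Technical triplicates are averaged within (gene, group, experiment);
then ΔCT = Ct(gene) − Ct(reference) per cell,
ΔΔCT = ΔCT(treated) − ΔCT(control) per experiment, and the
per-experiment fold change is `2^(−ΔΔCT)` (efficiency fixed at 2). The
reported fold change is the mean across experiments — the aggregation
order follows "average fold change from ≥ 3 independent experiments,
each in triplicate", which the source text states without fixing the
order; averaging replicates before differencing is the conventional
reading. The two-group test compares the per-experiment −ΔCT values
(log2 relative expression, on which the t-test is scale-invariant)
between groups with the classical equal-variance unpaired two-tailed t;
whether the published test ran on ΔCT or on fold changes is unstated,
and testing on the log scale was chosen because fold changes are
log-normal under the Ct error model. Degenerate inputs follow a
documented convention: both groups constant and equal → p = 1; pooled
variance zero with unequal means → p = 0. Reference-gene normalization
cancels any per-sample Ct offset exactly, which the suite asserts.

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 2000 genes, 6
paired batches, a 10% dysregulated fraction with fold-change magnitudes
uniform on [1.25, 3] and random sign, additive log2 batch effects
(SD 0.3) shared by a batch's two samples — the structure that makes
"batch was significant" reproducible — residual log2 noise (SD 0.25),
linear-scale export floored at 1.0, 2 kb promoters with i.i.d.
background, 5 TFs each planting one PWM-sampled site in 10% of genes at
uniform positions and strands (non-overlapping within a promoter, so
recorded ground truth always matches the sequence), and dysregulated
genes 3× as likely to be drawn as planted targets
(`de_target_weight = 3`), which is what makes TF-target enrichment in
the dysregulated set real rather than accidental. Sites are sampled from
the PWM's own per-position distribution so scanner recall and
enrichment p-values are nontrivial; a consensus-only override exists for
exact-recall tests. The published analysis states no noise or
effect-size magnitudes beyond the fold-change cutoff; the SDs and the
enrichment weight are the package's one-time choices of a realistic
regime for early-embryo arrays and are plainly overridable.

Deliberately *not* emulated: probe-level MAS5 internals (PM/MM probes,
detection p-values), array-specific spatial artefacts, correlated gene
modules, promoter sequence composition beyond 0-order, and TF identity
semantics (simulated PWMs are aliased to dysregulated gene ids so the
network stage has TF nodes). Passing tests therefore demonstrate that
the *pipeline machinery* is correct and calibrated under its stated
model — uniform null p-values, FDR control, exact scan p-values,
recoverable plants — not that real arrays satisfy the model.

## Problem sizes and tolerances

The test and verification runs use sizes chosen to keep the full suite
comfortably interactive while leaving Monte-Carlo bands tight: 20 seeds
of the default 2000-gene study for false-discovery and enrichment
recovery (binomial tolerance `1.96·sqrt(0.15·0.85/calls)` around the
nominal 0.15), 20 random PWMs of width ≤ 8 for the enumeration oracle,
the complete N ≤ 60 hypergeometric grid, 100 random vectors for the
Storey/BH identity, and 300 background-only 500-base promoters
(~3·10^5 windows) for scanner calibration at α = 1e-3, where the
empirical hit rate must not exceed α plus three binomial standard
errors (discreteness of the null keeps it below α).

## Known limitations

- The scanner's background is 0-order; higher-order Markov backgrounds
  (which absorb CpG and repeat structure in real promoters) are out of
  scope, so real-genome p-values will be anti-conservative in biased
  composition regions.
- π0 estimation with the smoother is unstable for very small probe sets
  (hundreds); the BH-equivalent `pi0 = 1` override is the conservative
  fallback.
- The balanced-paired ANOVA closed form requires exactly one sample per
  treatment-by-batch cell and refuses anything else; unbalanced designs
  would need the general linear-model route.
- Worked-example fixtures reproduce the published tables *as printed*,
  including their internal tensions (a 64-row TF table with 61 unique
  symbols; an enrichment table whose per-TF counts sum to 822 against a
  narrated 827-interaction network; a her7 fold change printed as −2.93
  but narrated as −2.51). The package documents these rather than
  reconciling them.
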