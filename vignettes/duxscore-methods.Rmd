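---
title: "duxscore: models, scores and design choices"
author: "duxscore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duxscore: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duxscore)
```

# The biological setting

FSHD muscle cells misexpress the embryonic transcription factor DUX4.
Because DUX4 bursts on sporadically — often in single nuclei — its activity
is measured through downstream target-gene programs rather than the DUX4
transcript itself. The analyses in this package answer three questions
about such a system: how strongly is the DUX4 program active in each sample,
does a compound suppress it, and at what concentration.

# The count model

Input is a gene-by-sample matrix of non-negative integer counts
(`DuxExperiment`, a `SummarizedExperiment` whose column annotation is the
sample sheet: state myoblast/myotube, treatment, dose in µM, replicate).

**Normalization.** Size factors are the median-of-ratios estimator:
for genes whose counts are positive in every sample, the geometric mean
$GM_g$ is accumulated in log space and $s_j = \mathrm{median}_g\,
c_{gj}/GM_g$. Any zero count excludes a gene from the reference set; the
median of an even number of reference genes is the arithmetic midpoint of
the two central ratios. Downstream scoring operates on
$\log_2(c_{gj}/s_j + 1)$; the pseudocount is configurable. No
variance-stabilizing or regularized-log transform is applied — the scores
are comparison-relative z-score averages, which are insensitive to
monotone per-gene rescaling, so the simpler transform suffices.

**Dispersion.** The negative binomial variance law is
$v = \mu + \alpha\mu^2$. Gene-wise dispersions come from method-of-moments
on normalized counts (pooled within-group residual variance), floored at
$10^{-8}$; a trend $\alpha(\mu) = a_0/\mu + a_1$ is fitted by least squares
with coefficients clamped at zero, and the final value is the log-scale
midpoint between the gene-wise estimate and the trend (weight 0.5,
configurable). The log scale is used because dispersions are positive and
multiplicative in effect; an arithmetic midpoint would be dominated by
occasional large gene-wise outliers.

**Wald test.** For a two-group contrast, each group's mean is fitted by
maximum likelihood with the dispersion fixed and offsets $\log s_j$
(the likelihood is strictly concave in $\beta = \log q$, so a damped Newton
iteration with score $\sum (y-\mu)/(1+\alpha\mu)$ and observed information
$\sum \mu(1+\alpha y)/(1+\alpha\mu)^2$ converges reliably). The statistic is
$\log_2FC / SE$ referred to the standard normal. This is a deliberate
simplification of full production DE tools — no Cox–Reid adjustment,
empirical-Bayes dispersion weights, LFC shrinkage, independent filtering or
outlier replacement — adequate because the package's purpose is the scoring
layer around a correct NB Wald test, not a DE tool clone. Genes with zero
counts in both groups report $\log_2FC = 0,\ p = 1$; zero in exactly one
group reports an infinite $\log_2FC$ with $p = 1$ and a flag, since without
a shrinkage prior the MLE is on the boundary. Significance calls use the
strict rule $|\log_2FC| > 1$ and $p_{adj} < 0.05$.

# Composite activity scores

**DUX4 score.** Each program gene present in the matrix is z-scored across
the samples of the comparison; the sample score is the mean z-score. The
z-scoring makes the units comparison-relative (they sum to zero across the
comparison) and prevents high-expressing genes from dominating a plain
mean of normalized counts. A `zscore = FALSE` switch preserves the
plain-mean reading. Genes missing from the matrix are dropped (reported via
`n_genes_used`); zero-variance genes are dropped with a warning.

**PAX7 score.** The per-sample t statistic comparing z-scored
PAX7-upregulated against PAX7-downregulated target genes. The Welch
(unequal-variance) form is the default; the originating composite-biomarker
method does not pin down the variant, so the pooled-variance Student form
is available by argument. Whether such scores should use log- or
linear-scale normalized data is equally open; log scale is the default
here because z-scores of log counts are far less skewed.

**Group comparisons.** One-way ANOVA plus many-to-one Dunnett comparisons
against the control. Adjusted p-values are computed by Monte-Carlo
integration of the multivariate-t null with the Dunnett correlation
$\rho_{ij} = \sqrt{n_i n_j/((n_i+n_0)(n_j+n_0))}$ (default $10^5$ draws,
seedable) rather than tabulated critical values; at the α levels used in
this field the Monte-Carlo error is negligible, and with exactly two groups
the comparison reduces to the unpaired Student t-test.

# Enrichment

The ranked list (by Wald statistic by default; log2FC or signed
$-\log_{10}p$ by argument — the ranking metric is a genuinely open choice,
as enrichment inputs are rarely reported precisely) is walked top to
bottom: hits add $|m|^p$ (normalized over hits), misses subtract
$1/(N-N_{hits})$; the ES is the signed extremum, with the positive extreme
winning exact magnitude ties. The null is **gene-set permutation**: with
triplicate groups only 10 distinct 3-vs-3 relabelings exist, so phenotype
permutation is degenerate at this scale; this is a deliberate deviation
from the enrichment tool's phenotype-permuting default. NES divides the ES
by the mean same-sign null |ES|; nominal p is the one-sided tail frequency
with +1 smoothing; FDR q follows the NES-pooling rule clamped to [0, 1];
defaults $p = 1$ weighting and 1,000 permutations. A set is significant at
nominal $p < 0.05$ and $q < 0.25$.

# Dose–response

The variable-slope four-parameter logistic is fitted on the log10-dose
axis by least squares with four heuristic starts (plateaus from the
response extremes; the IC50 start from the dose bracketing the half-range
crossing; hill at 0.5, 1 and 2) and bounds (IC50 within
[min dose/100, max dose·100], hill in (0, 10]); the best residual sum of
squares wins. Dose 0 never enters the fit — vehicle defines the
normalization constant. Replicate wells are fitted as individual points
rather than averaged: with a balanced design the least-squares optimum is
identical, and individual points keep the residual degrees of freedom
honest. Fitted IC50s outside the tested dose span, and fits whose
inhibition span is within the residual noise, are reported as a
"> max dose" sentinel, matching how potency tables mark uninhibited
markers.

# The synthetic experiment

The generator emulates the study conditions the analysis layer assumes:

- 5,000 genes; triplicate myoblast and myotube samples; one
  apabetalone-like compound on an eight-point geometric 0.02–50 µM grid
  with true IC50 1 µM and hill 1 (all configurable; additional compounds
  can be added to the drug list).
- Three DUX4 target programs of 150/100/80 genes with pairwise overlap
  fraction 0.3, mirroring how independently derived target lists overlap;
  PAX7 up/down programs of 50 genes each; 100 differentiation genes.
- Baseline log2 expression N(5, 2); NB dispersion trend
  $\alpha(\mu) = 2/\mu + 0.05$, typical of bulk RNA-seq at moderate depth;
  per-sample size factors log-uniform in [1/1.5, 1.5].
- Latent DUX4 activity $a$: 0 in myoblasts; a Bernoulli burst indicator in
  vehicle myotubes; $\mathrm{burst}/(1 + (dose/IC_{50})^{hill})$ under
  treatment. DUX4 targets scale by $2^{\beta a}$ with $\beta = 2$; the
  PAX7 up/down programs by $2^{\mp\gamma a}$ with $\gamma = 1$;
  differentiation genes by $2^2$ in all myotubes.
- `burstProb` defaults to 1: the literature describes bursting as sporadic
  and unpredictable but gives no rate, and a deterministic "on" state in
  vehicle myotubes makes parameter-recovery tests sharp. Sporadic bursting
  is available by lowering the probability.

The drug acts on the *latent activity*, not directly on counts, so
recovering the IC50 from the composite score is a genuine end-to-end test
of the whole chain. Bursting is modeled per replicate (whole-well on/off):
bulk RNA-seq averages nuclei, and the well is the unit of observation —
per-nucleus simulation is out of scope, as are batch effects, GC bias and
read-level simulation. Passing tests therefore demonstrate correctness of
the statistical machinery under NB noise with known structure; they do not
certify behavior under real-data pathologies (outlier samples, composition
effects, unmodeled covariates).

qPCR tables are generated by inverting the delta-CT rule
($CT_{marker} = CT_{ref} - \log_2 r$ + N(0, 0.15 cycles)); fusion tables
draw Poisson(100) nuclei per imaging field, three fields per sample, with
binomial fused counts.

# Numerical choices and degenerate inputs

- Geometric means accumulate in log space; a zero count excludes the gene
  from the size-factor reference set, and a matrix with no all-positive
  gene is an error rather than a silent fallback.
- The Newton iteration for NB means caps steps at ±5 log units; groups with
  zero total counts are flagged rather than fitted.
- The ES tie rule (positive extreme wins exact magnitude ties) makes
  results independent of summation order.
- Ranking ties break lexicographically by gene id, so rankings are
  deterministic and invariant to input row order.
- Undetermined qPCR CTs are excluded with a warning, never imputed.
- All simulators and permutation procedures are seedable and bit-stable
  under a fixed seed.

# Problem sizes used in the test suite

The suites validate against brute-force reimplementations on 100 random
small fixtures per statistic, calibrate type-I error on 2,000-gene null
simulations, the Dunnett family-wise error on 2,000 null repeats, and run
the full 5,000-gene synthetic experiment once; the whole suite completes in
well under a minute per file on a single CPU. These sizes give binomial
confidence intervals tight enough to detect meaningful miscalibration
while staying desk-scale.

# Known limitations

- The DE layer's simplifications (above) make its per-gene p-values less
  robust than production tools on real data with outliers or very low
  counts; at the simulated conditions it is correctly calibrated.
- The 25%-band coverage of the 4PL IC50 under 5% additive noise on the
  8-point triplicate grid is ~94% — the estimator's sampling sd there is
  ~0.13, so a ±25% band is only ±1.9 sd. This is a property of the design,
  not the optimizer (the fit matches a reference optimizer started at the
  truth).
- Composite scores are comparison-relative: scores computed in different
  comparisons are not on a common scale and must not be compared across
  runs.
- Gene identifiers are opaque case-sensitive strings; no identifier
  mapping is attempted.
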