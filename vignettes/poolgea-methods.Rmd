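---
title: "Methods: pool-seq genome-environment association with local-score zone detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq genome-environment association with local-score zone detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgea)
```

## The analysis

`poolgea` implements a genome-environment association (GEA) workflow for
pooled whole-genome sequencing of natural populations. One DNA pool is
sequenced per population, so per-SNP read counts estimate population
allele frequencies; the scientific question is which genomic regions track
ecological variation (pollinator visitation, climate, soil) across
populations, after accounting for the covariance that shared demographic
history induces among population allele frequencies.

The chain is: pooled VCF → count matrices and filters → allele
frequencies → among-population covariance Ω → whitened ("standardized")
frequencies → per-SNP XtX differentiation and per-variable Bayes factors →
rank-based pseudo p-values → Lindley local-score zones per scaffold →
tail-overlap enrichment against the XtX tail → candidate genes from a GFF3
annotation. A synthetic-data generator with known ground truth exercises
every stage.

## Core model

For SNP $j$ with across-population mean frequency $\pi_j$, the scaled
frequency of population $i$ is

$$y_{ij} = \frac{p_{ij} - \pi_j}{\sqrt{\pi_j(1-\pi_j)}},$$

and $\Omega = \mathrm{Cov}(y_{\cdot j})$ is the $K \times K$
among-population covariance capturing drift and shared history. With the
lower Cholesky factor $L L^\top = \Omega$, the whitened frequencies are
$z_j = L^{-1} y_j$, approximately $\mathcal N(0, I_K)$ under the null.

Two statistics are computed per SNP:

* **XtX** $= z_j^\top z_j$, a spatial differentiation index (an $F_{ST}$
  analogue) with null expectation $K$;
* **BFdB**, the Bayes factor in decibels for the linear association
  $z_j = \beta \tilde e + \varepsilon$, $\tilde e = L^{-1} e$ the whitened
  standardized covariate, $\beta \sim \mathcal N(0, \tau)$:

$$\mathrm{BF}_j = (1 + \tau\,\tilde e^\top \tilde e)^{-1/2}
  \exp\!\left(\frac{\tau\,(\tilde e^\top z_j)^2}
  {2(1 + \tau\,\tilde e^\top \tilde e)}\right),
  \qquad \mathrm{BFdB}_j = 10 \log_{10} \mathrm{BF}_j.$$

This is the exact conjugate closed form of the normal model (verified in
the test suite against numerical integration to relative $10^{-6}$).
Hierarchical MCMC machinery in the same spirit exists elsewhere; this
package deliberately uses the deterministic closed form: it preserves the
estimand structure (Ω-corrected association evidence in dB) while making
every run exactly reproducible. The `n_runs` averaging knob is therefore a
recorded no-op, and the 19-way chunking of the SNP set in `run_gea()`
mirrors a parallelization layout — Ω is estimated once, globally, so the
chunked scan is bit-identical to the unchunked one.

**Prior variance `tau`.** Default 0.1 (a weak effect prior on the whitened
standardized scale). SNP *ranking* by BFdB is invariant to `tau` for a
fixed covariate (the BF is monotone in $(\tilde e^\top z_j)^2$), so the
local-score and enrichment stages are insensitive to it; absolute dB
values are not, and should be reported together with `tau`.

## Estimating Ω, and what is identifiable

`estimate_omega()` uses the method of moments,
$\hat\Omega = \tfrac1L \sum_j y_j y_j^\top$, with mean-imputation of
missing cells (a missing pool contributes zero to $y$) and an optional
Ledoit-Wolf-style shrinkage toward the diagonal for small SNP sets.

Two numerical facts shape the implementation:

1. **The grand-mean direction is not identifiable.** When $\pi_j$ is the
   across-population mean, every column of $Y$ sums to zero, so
   $\hat\Omega$ is exactly rank $K-1$: the component of Ω along the
   all-ones vector is absorbed into $\pi$. A trace-scaled ridge
   ($10^{-6}\,\overline{\mathrm{diag}}$) is built into the estimator so
   the Cholesky factorization is always defined; the whitened statistics
   live in the $K-1$ informative dimensions regardless (the triangular
   solve isolates the lost degree of freedom in the last coordinate, so
   the empirical covariance of $z$ is $I - e_K e_K^\top$). If the true
   reference frequencies are known — as in simulations — passing them via
   `pi =` recovers Ω itself; block-structured covariances are recovered
   within a few percent Frobenius error at 50,000 SNPs.
2. **Degrees-of-freedom rescale of XtX.** Because one dimension is spent
   on centering, the raw sum of squares has null mean $K-1$; `xtx()`
   rescales by $K/(K-1)$ (flag `df_correct`) so the statistic is centered
   at $K$, its nominal null expectation. On a fully null simulation with
   21 populations this holds to three decimals.
3. **Clamps.** Simulated frequencies are clamped to $[0.005, 0.995]$
   (frequencies are generated on the natural scale, not through a logistic
   link, to match the linear geometry of the scaled-frequency model).
   When scaling, $\pi$ enters the denominator through
   $\sqrt{\pi(1-\pi)}$ clamped to $[0.01, 0.99]$ to avoid blow-ups at
   near-fixed sites, while centering keeps the exact mean so that scaled
   frequencies always sum to zero across populations.

## Pseudo p-values and the Lindley local score

Per-SNP scores are converted to pseudo p-values by ranking over the *full*
SNP set ($p_i = \mathrm{rank}_i / N$, rank 1 for the largest score, ties
broken by genomic position). Per scaffold, the site score is
$x_i = -\log_{10} p_i - \xi$ and the Lindley process is
$h_i = \max(0, h_{i-1} + x_i)$, reset at scaffold boundaries. With the
default $\xi = 3$ only SNPs with $p < 10^{-3}$ contribute positively, so
the process stays near zero under the null and climbs only where small
p-values cluster — which is how linkage around a selected or associated
site manifests. The recursion is implemented by the cumulative-sum
identity $h_i = S_i - \min(0, \min_{k \le i} S_k)$ and is tested against
the brute-force maximal-segment definition.

**Zone significance thresholds.** A zone is a maximal run of positive
$h$ whose peak exceeds a per-scaffold threshold; zones with fewer than
four SNPs (i.e. not more than three) are discarded before gene mapping.
The threshold is the $1-\alpha$ quantile of the null distribution of the
scaffold's maximum Lindley score. Three constructions are available:

* `resample` (default): draw `n_resample` tracks of i.i.d. uniform pseudo
  p-values of the scaffold's length — the exact null of rank-based pseudo
  p-values — and take the empirical quantile of their maxima;
* `permute`: within-scaffold permutation of the observed site scores;
* `gumbel`: moment fit of a Gumbel to the resampled maxima (smoother
  quantiles at small `n_resample`).

Resampling is the default for a concrete reason: at $\xi = 3$ a typical
null scaffold contains zero, one or two positively scoring sites, so the
permutation distribution of the maximum is almost degenerate (nearly every
rearrangement attains the same maximum — the largest single site score),
the observed maximum ties with the threshold, and the realized type-I rate
collapses far below $\alpha$. The Monte-Carlo uniform null is continuous
and calibrates correctly: in the test suite, the fraction of null
scaffolds whose observed maximum exceeds the threshold is within two
standard errors of $\alpha = 0.05$ over 400 scaffolds.

Whether the enrichment tails (below) are taken on Lindley scores or raw
BFdB is a genuine choice; the package defaults to Lindley-corrected
association scores and exposes raw BFdB as the alternative input.

## Tail-overlap enrichment with circular permutations

For each variable, the upper 0.05% tail of the association score is
intersected with the upper 0.05% tail of XtX
($\lceil N f \rceil$ SNPs each; boundary ties broken by position). Fold
enrichment is observed over the independence expectation $|A||B|/N$. The
null for the overlap count respects the positional clustering of the
association tail: each of `n_perm` (default 10,000) permutations rotates
set A by a uniform non-zero offset along the concatenated genome,
preserving its internal spacing, and the p-value uses the add-one
estimator $(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_\mathrm{perm}+1)$
— never zero, attaining its lower bound only when no rotation recreates
the observed overlap. Under an exchangeable null these p-values are
approximately uniform (KS-checked over 500 replicates in the test suite).
Stars mark $p < 0.05$, $< 0.01$, $< 0.001$.

## Candidate genes

Zones are 1-based inclusive intervals at the interface (half-open 0-based
in BED export). Candidates are all genes overlapping a zone by at least
1 bp plus the nearest non-overlapping gene on each side, strand-agnostic
(zones are not stranded; the flanking rule is applied per zone, not per
SNP). Upset-style exclusive intersections of per-variable candidate sets
decompose the union exactly, which the tests verify against powerset
enumeration.

## Ecological characterization

The visitation matrix (populations × 12 pollinator functional categories)
feeds eight species-level network indices per population, all in natural
log: normalized degree, species strength, species specificity (coefficient
of variation normalized by $\sqrt{C}$), Shannon partner diversity $H$,
effective partners $e^H$, proportional similarity, proportional
generality $e^H / e^{H(q)}$, and the Kullback-Leibler specialization
$d' = d / d_{\max}$ with $d = \sum_c p_c \ln(p_c/q_c)$, $d_{\min} = 0$
(attained exactly when a population's visit distribution $p$ equals the
availability $q$) and the analytic maximum $d_{\max} = \ln(1/\min_c q_c)$
(all visits on the rarest available partner). The continuous extremes are
used rather than integer-redistribution heuristics: they keep $d' = 0$
exactly at $p = q$ and are well defined for any nonnegative matrix.

Per-population visitation BLUPs come from the one-way random-effects model
$Y_i = \mu + \mathrm{population} + \varepsilon_i$ fitted by REML
(`lme4`); predictions follow the shrinkage form
$\mu + \hat\sigma^2_\mathrm{pop}/(\hat\sigma^2_\mathrm{pop} +
\hat\sigma^2_\mathrm{res}/n_k)\,(\bar y_k - \mu)$, interpolating between
the population mean and the grand mean. REML is preferred over moment
estimators because observed plants per population are few and unbalanced.

Redundant ecological variables are pruned by pairwise Spearman
correlation: pairs with $|\rho| \ge 0.8$ are scanned in a deterministic
order (descending $|\rho|$, then lexically) and the later-column member of
each still-offending pair is dropped. The order of resolution is a free
choice; the deterministic rule makes the retained set reproducible and
independent of population row order. Constant variables have undefined
rank correlations and are flagged and excluded from the decisions.

Ordinations: `env_pca()` works on the correlation matrix with a
deterministic sign convention (largest-magnitude loading positive);
`genomic_pc()` takes the SVD of the column-centered populations × SNPs
frequency matrix — population structure deliberately *uncorrected*, since
its purpose is to quantify how strongly each ecological variable aligns
with the leading axis of genomic variation (a diagnostic for confounding,
optionally with the `PC1 ~ latitude * longitude` model). The
eigenstructure of Ω itself is available directly from
`estimate_omega()$omega` for the structure-corrected view.

## The synthetic-data generator

Defaults emulate the study design the package targets: 21 populations;
ancestral frequencies uniform on (0.1, 0.9); population deviations
multivariate normal with covariance Ω (default: spatial decay
$0.05\,e^{-d/5}$ along a one-dimensional gradient — drift variance of
$F_{ST}$-like magnitude 0.05, typical of a regional population set);
pooled depth Poisson with mean 60 (the middle of the 6-100 retention
window, so the depth filter is exercised realistically); binomial read
sampling given depth; adaptive SNPs spiked in blocks of 10 adjacent sites
(frequency shift $\beta = 0.2$ per SD of the covariate by default) as a
stand-in for linkage around a causal site; an environmental covariate
built as a latitude-like gradient plus noise, optionally mixed with Ω's
leading eigenvector to emulate environment-structure confounding; and
negative-binomial visitation counts over the 12 pollinator functional
categories (Poisson in the dispersion → ∞ limit). The generator does
*not* simulate reads, mapping error, reference bias, or haplotype-level
LD; passing tests therefore demonstrate the statistical machinery under
its stated model, not robustness to alignment artifacts in real data. The
true genetic architecture (number and effect sizes of causal loci) is a
free parameter of the generator, not an empirical claim.

## Validation problem sizes

The package's own validation (test suite and `scripts/acceptance.R`) uses:
null calibration at 100,000 SNPs × 21 populations, depth 60 (mean XtX);
type-I calibration over 400 null scaffolds of 200 SNPs with 499
resampled thresholds each; power at 50,000 SNPs with 50 spiked SNPs in
five 10-SNP blocks; Ω recovery at 50,000 SNPs; permutation-p uniformity
over 500 replicates of 399 rotations. These sizes give stable Monte-Carlo
estimates at desk scale; all scale linearly if larger runs are wanted.

## Known limitations

* The Bayes factor is the conjugate closed form, not an MCMC posterior;
  dB values are comparable within a run but not numerically interchangeable
  with hierarchical-sampler output.
* Ω is identified only up to its grand-mean component when reference
  frequencies are estimated from the same populations (see above).
* No multiple-testing adjustment is applied across ecological variables;
  the enrichment table reports per-variable permutation p-values.
* Mean imputation of missing pools is adequate for the ≤2-population
  missingness the filters allow, and biased beyond it.
* The circular-permutation null assumes exchangeability of rotation
  offsets along the concatenated genome; scaffold boundaries are ignored
  by the rotation (standard for this construction).
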