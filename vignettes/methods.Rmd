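---
title: "Models and methods behind lactovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lactovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactovar)
```

# Scope

`lactovar` implements a quantitative-genetics pipeline for dissecting the
genetic architecture of milk production traits with mammary multi-omics
functional classes: defining classes from expression, miRNA and RNA-editing
evidence; partitioning phenotypic variance across classes with multi-GRM
REML; testing class enrichment against a circular-permutation null; and
feeding classes into genomic prediction (GBLUP, MultiBLUP, BayesR,
BayesRC).  Everything is exercised on a synthetic-data generator that
records its ground truth, so every estimator can be validated by recovery
tests without any external data.

# The variance-partitioning model

Phenotypes are deregressed predicted transmitting abilities (PTA divided by
squared reliability, removing parental information).  The base model is

$$y = 1\mu + \textstyle\sum_{f} g_f + \varepsilon,\qquad
  g_f \sim N(0, G_f \sigma^2_f),\quad \varepsilon \sim N(0, I\sigma^2_\varepsilon),$$

where each $G_f$ is a VanRaden (method 1) genomic relationship matrix
computed from the variants of functional class $f$:
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z$ the column-centred dosages and
$p_j$ the observed alternate-allele frequency.  The proportion of variance
explained by class $f$ is $h^2_f = \sigma^2_f/\sigma^2_P$, and per-class
enrichment is the odds ratio

$$\mathrm{enrichment}_f \;=\; \frac{h^2_f / h^2_{all}}{n_f / n},$$

with $h^2_{all}$ the sum of all fitted class proportions and $n_f/n$ the
class's share of the variant count.  A value of 1 means the class explains
exactly its per-variant share.

## REML algorithm and numerical choices

`fitREML()` maximizes the restricted likelihood with average-information
(AI) updates: one EM step first (robust far from the optimum), AI steps
thereafter, and step-halving whenever a step would decrease the
likelihood.  When an AI step would drive a component negative the
offending components are pinned at an effective zero
($10^{-8}\,\mathrm{var}(y)$) and the AI system is re-solved for the free
components; pinned components may re-enter later if their gradient turns
positive.  Convergence requires both a relative parameter change and a
log-likelihood change below `tol` (default $10^{-6}$).  Standard errors
come from the inverse AI matrix; standard errors of proportions use the
delta method on the full covariance.

With a single GRM the model is rotated once into the GRM's eigenbasis,
making every iteration $O(n)$ after an $O(n^3)$ eigendecomposition; with
several GRMs the dense $O(n^3)$-per-iteration path is used.  Both paths
maximize the same criterion and agree to numerical precision; the test
suite additionally pins the single-GRM path against an independent
closed-form grid search over $h^2$.

Deregressed PTAs are treated as homoskedastic by default: the reliability
weighting of residuals is a modelling option that the underlying study
design does not fix, and the synthetic generator's reliabilities are
informative only through the noise they inject.

## Overlap policy in multi-class fits

A variant may carry several annotations.  `partitionMulti()` assigns it to
the highest-priority class, priority being the order in which classes are
passed (defaulting to the map's order).  This keeps the GRMs disjoint, at
the cost of making the fitted proportions order-dependent when classes
overlap heavily; the warning on classes emptied by resolution makes that
visible.

# Circular-permutation null

To ask whether a site-derived class (e.g. flanks of RNA-editing sites)
explains more variance than position-matched chance, all sites are mapped
to a single circular coordinate by concatenating chromosomes
($\mathrm{cont} = \sum_{i<N} l_i + B$), advanced by one global uniform
draw $R \in [1, L]$, wrapped modulo $L$, and mapped back.  The shift
preserves the multiset of circular inter-site distances, hence the sites'
clustering structure — the key confounder a naive random-site null would
miss.  Flanking windows are re-expanded *after* shifting (sites are
shifted, not intervals), so a site crossing a chromosome boundary simply
adopts its new chromosome.  The empirical p-value uses add-one smoothing,
$p = (1 + \#\{h^2_{null} \ge h^2_{obs}\})/(n_{perm}+1)$, and is therefore
never zero; each permutation runs from an independent child stream of the
seed so the null is reproducible regardless of evaluation order.  The
published analysis reports only null means and standard deviations, so the
p-value convention is this package's own.

# Tissue-specificity t-statistics

For a target tissue, expression is regressed gene-by-gene on a design
whose first column is $+1$ for target samples and $-1$ for background
samples, plus intercept and covariates (project, breed, sex one-hot; age
numeric; single-observation levels merged, collinear columns dropped with
a warning).  The t-statistic is the tissue coefficient over its OLS
standard error; samples from tissue categories related to the target are
excluded so the background is strictly non-related tissue.  Specific genes
are the top 10% by t-statistic, ties at the cutoff included.

Normalization deserves a note.  The stated recipe — log2 transform then
"Z-score within each tissue" — is ambiguous.  Standardizing *every gene*
within every tissue would subtract exactly the tissue means the statistic
is built to detect, leaving pure noise; `preprocessExpression()` therefore
standardizes each tissue's samples jointly (one mean and SD over all of
that tissue's values), which equalizes scale across tissue batches while
preserving between-gene contrasts.  The per-gene variant is available via
`scope = "gene"` for diagnostics.  Genes with zero residual variance get
$t = 0$, are flagged degenerate, and can never enter the top fraction.

# miRNA prioritization

For each miRNA, Pearson correlations with all mRNAs are computed across
matched samples (two-sided p from the t approximation with $n-2$ df).  An
mRNA is "negatively correlated" when $r < 0$ and $p \le 0.05$ (inclusive,
as printed in the source material); the $2\times2$ table of negative
status against predicted-target status is tested with a one-sided Fisher
exact test (hypergeometric upper tail), since the question is enrichment.
A miRNA is a candidate when its Fisher $p < 0.05$ *and* the variance
proportion explained by its target-derived class exceeds $0.1$ — both
strict inequalities.  Target lists are inputs: no seed-match prediction is
implemented, matching the upstream use of dedicated target predictors.

# RNA-editing detection

The hyper-editing strategy: reads that fail to place on the reference
(more than 3 mismatches at their stated placement) are A-collapsed
(`A -> G`) along with the reference, realigned with an exact-seed plus
Hamming-extension matcher (leftmost tie-break, at most 2 transformed
mismatches, seed 20 bp), and then classified on the *original* alphabet.
A candidate read passes when its A-to-G mismatches (T-to-C counted on the
opposite strand; the library is unstranded) reach 5% of the read length —
at least 3 for reads of 60 bp or shorter — and exceed 80% of all
mismatches, mean Phred quality is above 25, ambiguous bases are at most
10%, and no mono-/di-nucleotide motif repeats more than 10 times nor any
homopolymer runs past 20 bp.  The repeat thresholds are configurable
because their operational definitions are not fixed by the source
description.

Editing level at a site combines both channels:
$(\mathrm{mapped\,G} + \mathrm{unmapped\,G}) / (\mathrm{mapped\,depth} +
\mathrm{unmapped\,G})$, zero when the denominator is zero.  Sites require
one passing hyper-edited read plus at least two edited reads in total —
the minimal support that suppresses false sites from isolated sequencing
errors while leaving low-level sites detectable.  Clusters chain
consecutive same-chromosome sites with gaps of at most 100 bp (boundary
inclusive).  Stage comparison calls a site stage-qualified when present in
every sample of a stage; differential testing of common sites uses the
Wilcoxon rank-sum on per-sample levels with Benjamini-Hochberg control at
0.05 (the original differential test is unstated; rank-sum is robust at
six-per-group sample sizes).

# Genomic prediction

GBLUP and MultiBLUP solve the mixed-model equations on the reference
block; validation animals receive GEBVs through their genomic
relationships with the reference ($\hat g = \sigma^2_g G_{\cdot,ref}
V_{ref}^{-1}(y-\hat\mu)$, and the two-component analogue).  GBLUP is
algebraically identical to SNP-BLUP at matched variances, which the tests
verify to $10^{-6}$ relative error.

BayesR places each SNP effect in a four-component mixture
$N(0, \gamma_k\sigma^2_\beta)$, $\gamma = (0, 0.01, 0.1, 1)$, sampled by
single-site Gibbs (RcppArmadillo); BayesRC gives every annotation class
its own mixture proportions with separate Dirichlet updates
($\alpha = 1$ per component).  Variances follow scaled-inverse-$\chi^2$
priors with $\nu = 4$; the $\sigma^2_\beta$ prior scale is set from a 50%
heritability guess spread over the markers, and the chain adapts from
there.  $\gamma_k$ scales a common sampled $\sigma^2_\beta$ — the variant
of BayesR in which component variances are fractions of a fixed genetic
variance differs by a constant factor absorbed into $\sigma^2_\beta$.
Posterior summaries are means over all post-burn-in samples (no
thinning).  Chains are reproducible: identical data, prior and seed give
identical trajectories, because all draws route through R's RNG.

Validation reliability is the squared Pearson correlation between GEBV
and validation deregressed PTA, in percent.  The source material never
defines its reliability; squared correlation is the simplest definition
consistent with its tables, and `compareModels()` computes per-trait
increases before any rounding (the printed per-trait increases carry
rounding artifacts of up to 0.01).

# The synthetic-data generator

The generator defines the study conditions for every test:

* **Genotypes** — unlinked biallelic variants, allele frequencies uniform
  on [0.05, 0.5] by default, dosages Binomial(2, p), positions uniform
  without replacement per chromosome.  No linkage disequilibrium is
  simulated; LD-dependent behaviour (pruning on real panels, shrinkage
  from tagging) is exercised only through duplicated columns.
* **Effects and phenotypes** — effects from the four-component mixture
  with class-specific proportions, genetic values rescaled post hoc so
  the realized $h^2$ equals the target exactly (the generative scale is
  otherwise unidentified); the default target 0.6 sits in the middle of
  the 0.71–0.89 range reported for milk traits at population scale while
  keeping desk-scale recovery tests well-conditioned.  PTA-like noise is
  $N(0, \sigma^2_e/r_i)$ with reliability $r_i$ uniform on [0.7, 0.99].
* **Expression panels** — N(0,1) log-scale baseline with planted
  mean-shift tissue-specific genes, plus project/breed/sex/age covariate
  columns.
* **miRNA systems** — anti-correlated true-target pairs at a stated
  correlation, embedded in noise target lists, mimicking the high false
  positive rate of sequence-based target prediction.
* **Edited reads** — reads tile the reference deterministically at the
  stated depth; planted sites (reference base forced to A) sit in
  clusters (default 6 sites spaced 5 bp).  Editing within a read is
  correlated through a shared propensity draw (processivity 0.85):
  molecules are either ADAR-processed — in which case each overlapped
  site is edited with probability ~0.85 — or untouched.  The marginal
  per-site editing probability equals the site's level exactly.  Without
  this correlation a site at level 0.2 would almost never sit on a read
  with enough A-to-G mismatches to be recovered by the hyper-editing
  route, and the detector's stated operating point (sensitivity and
  precision at least 0.9 at level 0.2 and depth 30) would be
  unreachable; processive editing is also what the hyper-editing method
  exploits in real data.

What the generator does *not* emulate — LD structure, pedigree,
population stratification, non-uniform error profiles, expression
count-noise — bounds what passing tests show: they validate the
estimators' logic and calibration under their own assumptions, not
robustness to the full messiness of real cattle data.

# Problem sizes used by tests and the acceptance script

Heritability recovery runs at n = 2000 individuals and m = 5000 variants
(20 replicates in the test suite, 5 in the script); partition recovery at
n = 800, m = 2000; permutation calibration at n = 150, m = 600 with 19
permutations and 200 replicates (simulated heritability 0.8 and 100 kb
flanks keep the class variance clear of the REML zero boundary, whose
ties would otherwise distort the null p-distribution); prediction
comparisons at n = 625
(500 reference / 125 validation), m = 2000 with 5000 MCMC iterations and
1000 burn-in, scaled down from the 25,000/5,000 used at population scale.
These sizes keep every stochastic check's Monte-Carlo error well inside
its assertion margin.

# Known limitations

* No LD simulation, so enrichment estimates on synthetic data do not
  display the tagging-induced smearing seen with sequence data.
* `ldPrune()` is quadratic in window occupancy and meant for desk-scale
  panels, not millions of variants.
* The editing realigner is ungapped by design; spliced or indel-bearing
  reads are out of scope.
* Reliability weighting of deregressed PTAs and fixed covariates beyond
  the overall mean are not modelled (available hooks: phenotype columns
  pass through unchanged).
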