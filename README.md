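# lactovar

Partitioning the genetic variance of milk production traits across
mammary multi-omics functional classes, and using those classes to
inform genomic prediction in dairy cattle.

Complex dairy traits are controlled by thousands of variants whose
effects concentrate in functionally annotated parts of the genome —
genes specifically expressed in lactating mammary tissue, differentially
expressed genes and miRNAs, RNA-editing clusters, enhancers, eQTLs and
sQTLs.  `lactovar` implements the quantitative machinery to measure that
concentration and exploit it:

* **GRM construction and genotype QC** — VanRaden method 1,
  `G = ZZ'/(2Σ p_j(1−p_j))`, with call-rate/MAF/HWE filtering, LD
  pruning (r² threshold) and panel merging.
* **Multi-GRM variance partitioning** — AI-REML for
  `y = 1μ + Σ_f g_f + ε`, `g_f ~ N(0, G_f σ²_f)`, giving per-class
  proportions `h²_f = σ²_f/σ²_P` and enrichment odds ratios
  `(h²_f/h²_all)/(n_f/n)`; two-GRM (class vs rest), many-class and
  per-chromosome designs.
* **Circular-permutation null** — sites are shifted by one uniform draw
  along the concatenated-genome circle, preserving their clustering, and
  the class variance is refit per shift; empirical p with add-one
  smoothing.
* **Functional-class definition statistics** — tissue-specificity
  t-statistics from ±1-coded OLS with covariates and related-tissue
  exclusion; miRNA–target anti-correlation with one-sided Fisher
  enrichment and the dual-criterion candidate rule (Fisher p < 0.05 and
  target-class h² > 0.1); hyper-editing A-to-I detection (A-collapse,
  realignment, read filters), editing levels
  `(mapped G + unmapped G)/(mapped depth + unmapped G)`, 100 bp cluster
  calling and lactation-stage comparison.
* **Genomic prediction** — GBLUP, MultiBLUP, and BayesR/BayesRC with the
  four-component mixture prior `N(0, γ_k σ²_β)`, `γ = (0, 0.01, 0.1, 1)`
  (Gibbs sampler in compiled code; BayesRC learns class-specific mixing
  proportions), plus deregression (PTA/reliability²), reference/validation
  splitting by birth year, validation reliability (squared correlation,
  %), and the reliability-comparison arithmetic of the published tables.
* **Synthetic data with ground truth** — genotypes, mixture effects and
  PTA-like phenotypes at an exact target h², expression panels with
  planted specific genes, miRNA systems with planted regulators, and
  reads with planted editing at known levels, so every estimator is
  validated by recovery tests.

## Worked example

Simulate a panel with effects planted in one functional class, partition
the variance, and test the class against the circular null:

```r
library(lactovar)

gm  <- simGenotypes(500, 1200, chromLengths = c(chr1 = 5e6, chr2 = 5e6),
                    seed = 3)
cls <- buildClassMap(gm, intervalSets = list(
         funct = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e6))))
sim <- simEffectsAndPhenotypes(gm, cls,
         classPi = list(funct = c(0.8, 0, 0, 0.2),    # 20% non-null inside
                        other = c(1, 0, 0, 0)),       # null outside
         h2Target = 0.6, seed = 4)

fit <- partitionTwo(sim$phenotypes, gm, cls, "funct")
fit
#> VarCompFit (converged, 8 iterations, n = 500)
#>   funct                sigma2 = 1.649  h2 = 0.6481 (se 0.0556)
#>   other                sigma2 = 0  h2 = 0.0000 (se 0.0459)
#>   residual             sigma2 = 0.8953
#>   h2(all) = 0.6481   logLik = -899.107
```

All planted genetic variance is assigned to the class that truly carries
it (`h²_funct ≈ 0.65` against a simulated target of 0.6, `h²_other` pinned
at zero).  Enrichment follows directly; with the class holding half the
variants, values near 2 mean "all signal, half the variants":

```r
enrichment(fit, counts = lengths(classMembers(cls))[names(varComponents(fit))[1:2]])
#>   class      h2_f    h2_all n_f    n enrichment
#> 1 funct 0.6481187 0.6481187 600 1200          2
#> 2 other 0.0000000 0.6481187 600 1200          0
```

The same arithmetic reproduces the published ten-class bookkeeping: the
per-class variance proportions for milk fat percentage sum to 0.839, and
the sQTL class (55,166 of 3,026,716 variants explaining 0.305 of that
0.839) is ~20-fold enriched:

```r
cls10 <- milkClassProportions()
sum(cls10$MFP)
#> [1] 0.839
(0.305 / 0.839) / (55166 / 3026716)
#> [1] 19.94518
```

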