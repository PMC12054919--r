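test_that("qcFilter applies boundary-inclusive MAF, call-rate and HWE rules in order", {
  n <- 1000
  set.seed(21)
  d <- cbind(
    maf04 = rbinom(n, 2, 0.04),
    maf05 = rbinom(n, 2, 0.05) + 0L,
    common = rbinom(n, 2, 0.3),
    allhet = rep(1L, n))
  # force the 0.05 column to exactly MAF 0.05 and the 0.04 below threshold
  d[, "maf05"] <- c(rep(1L, n * 0.1), rep(0L, n * 0.9))
  d[, "maf04"] <- c(rep(1L, 80), rep(0L, n - 80))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4 * 100, width = 1),
                               id = colnames(d))
  gm <- GenotypeMatrix(matrix(d, n, 4,
                              dimnames = list(sprintf("s%04d", 1:n),
                                              colnames(d))), gr)
  out <- qcFilter(gm)
  expect_true("maf05" %in% variantIds(out))   # MAF exactly 0.05 retained
  expect_false("maf04" %in% variantIds(out))  # below threshold removed
  # all-heterozygote variant: HWE chi-square equals n, p << 1e-6
  expect_false("allhet" %in% variantIds(out))
  expect_lt(pchisq(n, df = 1, lower.tail = FALSE), 1e-6)

  # clean panel passes unchanged, and qcFilter is idempotent
  clean <- fixSmallPanel(n = 200, m = 50, seed = 22)
  f1 <- qcFilter(clean)
  expect_identical(dosages(qcFilter(f1)), dosages(f1))
})

test_that("computeGRM matches the direct VanRaden arithmetic oracle", {
  d <- matrix(c(0, 1, 2, 1,
                2, 1, 0, 1,
                1, 1, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:4, width = 1),
                               id = paste0("v", 1:4))
  gm <- GenotypeMatrix(d, gr)
  G <- grmMatrix(computeGRM(gm))

  # oracle: explicit centring and normalization, written independently
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(d[, poly], 2, 2 * p[poly])
  expected <- Z %*% t(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  expect_equal(G, expected, ignore_attr = TRUE, tolerance = 1e-12)

  # identical individuals have identical relationships
  expect_equal(G["a", "a"], G["a", "a"])
  d2 <- d[c(1, 1, 2), ]
  rownames(d2) <- c("a", "b", "c")
  G2 <- grmMatrix(computeGRM(GenotypeMatrix(d2, gr)))
  expect_equal(G2["a", "b"], G2["a", "a"], tolerance = 1e-12)
})

test_that("GRM is PSD, invariant to panel duplication, with sensible diagonal", {
  gm <- fixSmallPanel(n = 80, m = 200, seed = 23)
  G <- computeGRM(gm)
  ev <- eigen(grmMatrix(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * sum(diag(grmMatrix(G))) / nSamples(gm))
  expect_lt(abs(mean(diag(grmMatrix(G))) - 1), 0.1)

  # duplicating every variant leaves G unchanged
  d <- dosages(gm)
  v <- variantRanges(gm)
  v2 <- v
  v2$id <- paste0(v2$id, "dup")
  GenomeInfoDb::seqlengths(v2) <- NA
  dd <- cbind(d, d)
  colnames(dd) <- c(v$id, v2$id)
  gm2 <- GenotypeMatrix(dd, suppressWarnings(c(v, v2)))
  expect_equal(grmMatrix(computeGRM(gm2)), grmMatrix(G), tolerance = 1e-10)

  mono <- GenotypeMatrix(matrix(2, 3, 2, dimnames = list(c("a", "b", "c"),
                                                         c("m1", "m2"))),
                         GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(1:2, width = 1),
                           id = c("m1", "m2")))
  expect_error(computeGRM(mono), "monomorphic")
})

test_that("missing dosages are mean-imputed before GRM construction", {
  gm <- fixSmallPanel(n = 50, m = 80, seed = 24)
  d <- dosages(gm)
  dNA <- d
  dNA[sample(length(dNA), 200)] <- NA
  gmNA <- GenotypeMatrix(dNA, variantRanges(gm))
  G <- computeGRM(gmNA)
  expect_true(all(is.finite(grmMatrix(G))))
  expect_s4_class(G, "GRM")
})

test_that("ldPrune drops the later of a duplicated pair and keeps independent variants", {
  gm <- fixSmallPanel(n = 100, m = 60, seed = 25)
  d <- dosages(gm)
  v <- variantRanges(gm)
  # duplicate column 5 at a later position on the same chromosome
  dup <- d[, 5]
  d2 <- cbind(d, dup = dup)
  vdup <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(GenomicRanges::start(v)[5] + 1000, width = 1),
            id = "dupvar")
  GenomeInfoDb::seqlengths(vdup) <- NA
  v2 <- suppressWarnings(c(v, vdup))
  colnames(d2) <- c(v$id, "dupvar")
  gmd <- GenotypeMatrix(d2, v2)
  pruned <- ldPrune(gmd, r2Max = 0.9)
  expect_true(v$id[5] %in% variantIds(pruned))
  expect_false("dupvar" %in% variantIds(pruned))

  # unlinked simulated panel survives nearly intact
  p2 <- ldPrune(gm, r2Max = 0.9)
  expect_gte(nVariants(p2), nVariants(gm) - 2)

  # r2Max = 1 removes nothing but exact duplicates
  expect_identical(nVariants(ldPrune(gm, r2Max = 1)), nVariants(gm))
})

test_that("mergePanels takes the union keyed by position/alleles, keeping base copies", {
  gm <- fixSmallPanel(n = 20, m = 15, seed = 26)
  base <- gm[, 1:10]
  extra <- gm[, 6:15]
  merged <- mergePanels(base, extra)
  expect_identical(nVariants(merged), 15L)
  expect_identical(nVariants(mergePanels(gm, base)), 15L)  # subset: no-op

  disjointA <- gm[, 1:10]
  disjointB <- gm[, 11:15]
  expect_identical(nVariants(mergePanels(disjointA, disjointB)), 15L)

  other <- fixSmallPanel(n = 21, m = 15, seed = 27)
  expect_error(mergePanels(base, other), "same samples")
})

test_that("class maps use half-open BED semantics, flanking and clipping", {
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(150, 200, 201), width = 1),
          id = c("in1", "boundary", "out"))
  gm <- GenotypeMatrix(matrix(1, 2, 3,
                              dimnames = list(c("s1", "s2"),
                                              c("in1", "boundary", "out"))), gr)
  # BED interval [100, 200) -> 1-based closed [101, 200]
  bed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  cm <- buildClassMap(gm, intervalSets = list(cls = bed))
  expect_setequal(classMembers(cm)$cls, c("in1", "boundary"))
  expect_setequal(classMembers(cm)$other, "out")

  # flanking reaches a variant at position 1 after clipping at the bound
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = 1),
                                id = "v1")
  gm2 <- GenotypeMatrix(matrix(1, 2, 1, dimnames = list(c("s1", "s2"), "v1")),
                        far)
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1001))
  cm2 <- buildClassMap(gm2, intervalSets = list(cls = iv), flankBp = 5000)
  expect_identical(classMembers(cm2)$cls, "v1")

  # full coverage leaves an empty complement
  all <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  cm3 <- buildClassMap(gm, intervalSets = list(a = all, b = all))
  expect_length(classMembers(cm3)$other, 0)

  bad <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10))
  expect_error(buildClassMap(gm, intervalSets = list(x = bad)),
               "unknown chromosome")
})
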