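test_that("A-collapse transform follows the rule and is idempotent", {
  expect_identical(hyperEditTransform("AACGT"), "GGCGT")
  expect_identical(hyperEditTransform("CGTCG"), "CGTCG")
  s <- "ATTACGGA"
  expect_identical(hyperEditTransform(hyperEditTransform(s)),
                   hyperEditTransform(s))
  expect_error(hyperEditTransform("ACGU"), "non-DNA")
})

test_that("realignment places transformed reads with leftmost tie-breaking", {
  ref <- c(ref = paste(rep("ACGTTGCA", 40), collapse = ""))
  # a perfect substring aligns with zero mismatches at its position
  sub <- substr(unname(ref), 33, 72)
  aln <- realignTransformed(
    data.frame(read_id = "r1", seq = sub), ref)
  # repeated reference: the leftmost equivalent placement is chosen
  expect_identical(aln$pos %% 8L, 1L)
  expect_identical(aln$mismatches, 0L)
  expect_lte(aln$pos, 33L)

  # planted A->G differences vanish after the transform
  edited <- chartr("A", "G", sub)
  aln2 <- realignTransformed(
    data.frame(read_id = "r2", seq = edited), ref)
  expect_identical(aln2$mismatches, 0L)

  # an unrelated sequence is discarded
  aln3 <- realignTransformed(
    data.frame(read_id = "r3",
               seq = paste(rep("T", 40), collapse = "")), ref)
  expect_identical(nrow(aln3), 0L)
})

test_that("candidate-read classification implements the printed filter rules", {
  mk <- function(len, nAG, nOther, qualPhred = 30) {
    set.seed(len + nAG * 7 + nOther)         # repeat-free random reference
    rf <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    rd <- rf
    agIdx <- which(rf == "A")[seq_len(nAG)]
    rd[agIdx] <- "G"
    if (nOther > 0) {
      otherIdx <- which(rf == "C")[seq_len(nOther)]
      rd[otherIdx] <- "T"
    }
    list(read = paste(rd, collapse = ""), ref = paste(rf, collapse = ""),
         qual = paste(rep(rawToChar(as.raw(qualPhred + 33)), len),
                      collapse = ""))
  }

  # 100 bp, 5 A->G, nothing else: 5 >= ceil(0.05*100) and 5/5 > 0.8
  x <- mk(100, 5, 0)
  expect_true(classifyCandidateRead(x$read, x$ref, x$qual)$pass)

  # 50 bp needs >= 3 A->G
  y2 <- mk(50, 2, 0)
  expect_false(classifyCandidateRead(y2$read, y2$ref, y2$qual)$pass)
  y3 <- mk(50, 3, 0)
  expect_true(classifyCandidateRead(y3$read, y3$ref, y3$qual)$pass)

  # 5 A->G with 2 other mismatches: 5/7 <= 0.8 fails the purity rule
  z <- mk(100, 5, 2)
  expect_false(classifyCandidateRead(z$read, z$ref, z$qual)$pass)

  # low quality fails
  lowq <- mk(100, 6, 0, qualPhred = 20)
  expect_false(classifyCandidateRead(lowq$read, lowq$ref, lowq$qual)$pass)

  # N fraction above 10% fails
  w <- mk(100, 6, 0)
  rd <- strsplit(w$read, "")[[1]]
  rd[90:100] <- "N"
  expect_false(classifyCandidateRead(paste(rd, collapse = ""), w$ref,
                                     w$qual)$pass)

  # homopolymer run beyond the limit fails
  hp <- classifyCandidateRead(
    paste0(paste(rep("T", 25), collapse = ""),
           chartr("A", "G", paste(rep("AC", 10), collapse = ""))),
    paste0(paste(rep("T", 25), collapse = ""),
           paste(rep("AC", 10), collapse = "")),
    NULL)
  expect_false(hp$pass)

  expect_error(classifyCandidateRead("ACG", "AC"), "length mismatch")
})

test_that("editing level follows its defining formula and bounds", {
  expect_equal(editingLevel(3, 2, 8), 0.5)
  expect_equal(editingLevel(0, 0, 20), 0)
  expect_equal(editingLevel(10, 0, 10), 1)
  expect_equal(editingLevel(0, 0, 0), 0)
  expect_error(editingLevel(-1, 0, 5), "nonnegative")
  expect_error(editingLevel(6, 0, 5), "exceeds")

  # bounded and monotone over a grid of valid counts
  for (mg in 0:5) for (ug in 0:5) for (md in 5:7) {
    l <- editingLevel(mg, ug, md)
    expect_gte(l, 0); expect_lte(l, 1)
    expect_gte(editingLevel(min(mg + 1, md), ug, md), l)
    expect_gte(editingLevel(mg, ug + 1, md), l)
  }
})

test_that("strand collapse relabels and merges T-to-C sites", {
  s <- data.frame(chrom = "ref", pos = c(10, 10, 20),
                  type = c("A-to-G", "T-to-C", "T-to-C"),
                  mapped_G = c(4, 2, 1), unmapped_G = c(1, 1, 0),
                  mapped_depth = c(10, 6, 5))
  out <- collapseStrand(s)
  expect_identical(nrow(out), 2L)
  expect_true(all(out$type == "A-to-G"))
  merged <- out[out$pos == 10, ]
  expect_identical(merged$mapped_G, 6)
  expect_identical(merged$mapped_depth, 16)

  pure <- data.frame(chrom = "ref", pos = 5, type = "A-to-G",
                     mapped_G = 1, unmapped_G = 0, mapped_depth = 2)
  expect_identical(collapseStrand(pure)[names(pure)], pure)
})

test_that("cluster calling chains sites at the 100 bp boundary", {
  sites <- data.frame(chrom = "ref", pos = c(1, 50, 140, 300))
  cl <- callClusters(sites)$clusters
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$start, c(1, 300))
  expect_identical(cl$end, c(140, 300))
  expect_identical(cl$n_sites, c(3L, 1L))

  # boundary inclusive at exactly 100; split at 101
  expect_identical(nrow(callClusters(
    data.frame(chrom = "r", pos = c(0, 100)))$clusters), 1L)
  expect_identical(nrow(callClusters(
    data.frame(chrom = "r", pos = c(0, 101)))$clusters), 2L)

  # different chromosomes never chain
  two <- callClusters(data.frame(chrom = c("c1", "c2"), pos = c(1, 5)))
  expect_identical(nrow(two$clusters), 2L)

  expect_warning(callClusters(data.frame(chrom = "r", pos = c(50, 1))),
                 "not sorted")
})

test_that("planted sites are recovered with calibrated levels", {
  fx <- simEditedReads(4000, nSites = 30, levels = rep(c(0.3, 0.7), 15),
                       depth = 50, readLength = 50, errorRate = 0.001,
                       seed = 96)
  det <- detectEditingSites(fx$reads, fx$reference)
  tp <- sum(det$sites$pos %in% fx$truth$pos)
  expect_gte(tp / nrow(fx$truth), 0.9)
  expect_gte(tp / nrow(det$sites), 0.9)
  # binomial sampling at depth 50 bounds the per-site level error
  m <- merge(det$sites, fx$truth, by = "pos")
  err <- abs(m$level.x - m$level.y)
  expect_lt(mean(err), 0.08)
  expect_lte(unname(quantile(err, 0.9)), 0.15)

  # full editing, no errors: every overlapping read carries G
  full <- simEditedReads(1500, nSites = 6, levels = 1, depth = 30,
                         readLength = 50, errorRate = 0, seed = 97)
  detF <- detectEditingSites(full$reads, full$reference)
  expect_setequal(detF$sites$pos, full$truth$pos)
  expect_true(all(detF$sites$level == 1))
})

test_that("stage comparison classifies specific, common and differential sites", {
  mkTable <- function(positions, levels) {
    data.frame(chrom = "ref", pos = positions, level = levels)
  }
  set.seed(98)
  samples <- list()
  for (i in 1:6) # lactating: sites 100 (lvl ~0.2), 200 (~0.5)
    samples[[paste0("L", i)]] <- mkTable(c(100, 200),
                                         c(0.2, 0.5) + runif(2, -0.02, 0.02))
  for (i in 1:6) # dry: sites 100 (lvl ~0.8), 300
    samples[[paste0("D", i)]] <- mkTable(c(100, 300),
                                         c(0.8, 0.4) + runif(2, -0.02, 0.02))
  groups <- setNames(rep(c("lact", "dry"), each = 6),
                     c(paste0("L", 1:6), paste0("D", 1:6)))
  res <- compareStages(samples, groups)
  expect_setequal(res$common$pos, 100)
  expect_setequal(res$specific$pos, c(200, 300))
  expect_identical(res$specific$stage[res$specific$pos == 200], "lact")
  # site 100 differs strongly between stages
  expect_true(100 %in% res$differential$pos)

  # identical level distributions are not flagged
  same <- samples
  for (nm in names(same)) same[[nm]]$level <- 0.5
  resSame <- compareStages(same, groups)
  expect_identical(nrow(resSame$differential), 0L)

  oneStage <- setNames(rep("lact", 12), names(groups))
  expect_error(compareStages(samples, oneStage), "two stages")
  expect_error(compareStages(samples, groups[1:6]), "cover every sample")
})
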