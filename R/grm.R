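#' Genotype quality control
#'
#' Filters a genotype panel in the fixed order: sample call rate, variant
#' call rate, minor allele frequency, Hardy-Weinberg equilibrium.  All
#' thresholds are boundary-inclusive for retention (a variant at exactly
#' \code{mafMin} is kept; a variant with HWE p exactly \code{hwePmin} is
#' kept).  HWE is tested with a 1-df chi-square on the three genotype
#' counts against Hardy-Weinberg proportions at the observed allele
#' frequency.
#'
#' @param geno a \linkS4class{GenotypeMatrix} (may contain \code{NA}).
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param callrateMin minimum call rate for both samples and variants
#'   (default 0.90).
#' @param hwePmin minimum HWE p-value (default 1e-6).
#' @return the filtered \linkS4class{GenotypeMatrix}.
#' @export
qcFilter <- function(geno, mafMin = 0.05, callrateMin = 0.90,
                     hwePmin = 1e-6) {
  d <- dosages(geno)

  keepS <- rowMeans(!is.na(d)) >= callrateMin
  d <- d[keepS, , drop = FALSE]
  if (nrow(d) == 0) stop("no samples pass the call-rate filter")

  cr <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwep <- hweChisqP(d)
  keepV <- cr >= callrateMin & maf >= mafMin &
    (is.na(hwep) | hwep >= hwePmin)
  if (!any(keepV)) stop("no variants pass QC")

  GenotypeMatrix(d[, keepV, drop = FALSE], variantRanges(geno)[keepV])
}

# 1-df chi-square HWE p-value per variant (columns of dosage matrix)
hweChisqP <- function(d) {
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  chi <- rep(NA_real_, length(n))
  ok <- e0 > 0 & e1 > 0 & e2 > 0
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] + (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  ifelse(is.na(chi), NA_real_, stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Compute a VanRaden (method 1) genomic relationship matrix
#'
#' \eqn{G = ZZ'/(2\sum_j p_j(1-p_j))} where \eqn{Z} is the dosage matrix
#' centred by twice the observed alternate-allele frequency.  Missing
#' dosages are mean-imputed per variant first; monomorphic variants are
#' excluded from both numerator and denominator.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @return a \linkS4class{GRM}.
#' @export
computeGRM <- function(geno) {
  stopifnot2(nSamples(geno) >= 2, "need >= 2 individuals")
  d <- dosages(geno)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all variants are monomorphic")
  Z <- sweep(d[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  new("GRM", mat = G, nVariantsUsed = sum(poly))
}

#' Compute a GRM from a named variant subset
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param ids variant IDs to use.
#' @return a \linkS4class{GRM}.
#' @export
grmFromIds <- function(geno, ids) {
  j <- match(ids, variantIds(geno))
  stopifnot2(!anyNA(j), "unknown variant IDs")
  stopifnot2(length(j) >= 1, "empty variant set")
  computeGRM(geno[, j])
}

#' Greedy LD pruning
#'
#' Left-to-right scan within a sliding physical window: when a pair of
#' variants has squared Pearson dosage correlation above \code{r2Max},
#' the later (higher-position) variant is dropped and the earlier kept.
#' Deterministic and order-stable; output preserves the original variant
#' order.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param r2Max squared-correlation threshold; pairs with \eqn{r^2 >
#'   r2Max} trigger a drop (default 0.9).
#' @param windowBp physical window in bp (default 1e6).
#' @return the pruned \linkS4class{GenotypeMatrix}.
#' @export
ldPrune <- function(geno, r2Max = 0.9, windowBp = 1e6) {
  d <- dosages(geno)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  v <- variantRanges(geno)
  chrom <- as.character(seqnames(v))
  pos <- start(v)
  m <- ncol(d)
  keep <- rep(TRUE, m)
  sds <- apply(d, 2, stats::sd)
  for (j in seq_len(m)) {
    if (!keep[j]) next
    k <- j - 1L
    while (k >= 1L) {
      if (chrom[k] != chrom[j] || pos[j] - pos[k] > windowBp) break
      if (keep[k] && sds[j] > 0 && sds[k] > 0 &&
          stats::cor(d[, j], d[, k])^2 > r2Max) {
        keep[j] <- FALSE
        break
      }
      k <- k - 1L
    }
  }
  geno[, which(keep)]
}

#' Merge two genotype panels over the same samples
#'
#' Union of variants keyed by (chromosome, position, ref, alt); variants
#' present in both panels keep the \code{base} copy.  Output is sorted by
#' position.
#'
#' @param base,extra \linkS4class{GenotypeMatrix} objects sharing the
#'   same sample IDs.
#' @return the merged \linkS4class{GenotypeMatrix}.
#' @export
mergePanels <- function(base, extra) {
  stopifnot2(setequal(sampleIds(base), sampleIds(extra)),
             "panels must cover the same samples")
  extra <- extra[match(sampleIds(base), sampleIds(extra)), ]
  keyOf <- function(g) {
    v <- variantRanges(g)
    paste(as.character(seqnames(v)), start(v), v$ref, v$alt, sep = ":")
  }
  kb <- keyOf(base); ke <- keyOf(extra)
  add <- which(!(ke %in% kb))
  if (length(add) == 0) return(base)
  vb <- variantRanges(base); ve <- variantRanges(extra)[add]
  # resolve variant-ID clashes from the extra panel
  dup <- ve$id %in% vb$id
  ve$id[dup] <- paste0(ve$id[dup], ".x")
  d <- cbind(dosages(base), dosages(extra)[, add, drop = FALSE])
  colnames(d) <- c(vb$id, ve$id)
  GenotypeMatrix(d, suppressWarnings(c(vb, ve)))
}
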