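#' Correlate miRNAs with their predicted target mRNAs
#'
#' Pearson correlation and two-sided p-value (t approximation with n - 2
#' df) for every requested (miRNA, mRNA) pair over matched samples.
#' Pairs involving a zero-variance series are flagged and excluded from
#' downstream counting.
#'
#' @param mirnaExpr miRNAs x samples matrix.
#' @param mrnaExpr mRNAs x samples matrix over the same samples (same
#'   column order).
#' @param pairs data.frame with columns \code{mirna_id}, \code{mrna_id};
#'   default: all miRNA x mRNA combinations.
#' @return data.frame: mirna_id, mrna_id, r, p, negative (r < 0 and p <=
#'   0.05), excluded.
#' @export
correlateTargets <- function(mirnaExpr, mrnaExpr, pairs = NULL) {
  stopifnot2(ncol(mirnaExpr) == ncol(mrnaExpr),
             "matrices must share the sample set")
  n <- ncol(mirnaExpr)
  stopifnot2(n >= 3, "need >= 3 samples")
  if (is.null(pairs))
    pairs <- expand.grid(mirna_id = rownames(mirnaExpr),
                         mrna_id = rownames(mrnaExpr),
                         stringsAsFactors = FALSE)

  x <- mirnaExpr[pairs$mirna_id, , drop = FALSE]
  y <- mrnaExpr[pairs$mrna_id, , drop = FALSE]
  vx <- apply(x, 1, stats::sd)
  vy <- apply(y, 1, stats::sd)
  excluded <- vx == 0 | vy == 0
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) /
    sqrt(pmax(rowSums(xc^2) * rowSums(yc^2), .Machine$double.xmin))
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  r[excluded] <- NA_real_; p[excluded] <- NA_real_

  data.frame(mirna_id = pairs$mirna_id, mrna_id = pairs$mrna_id,
             r = unname(r), p = unname(p),
             negative = !excluded & !is.na(r) & r < 0 & p <= 0.05,
             excluded = unname(excluded), stringsAsFactors = FALSE)
}

#' Fisher enrichment of negatively correlated mRNAs among targets
#'
#' 2x2 contingency table over the mRNA universe: negatively correlated
#' (r < 0 and correlation p <= 0.05) vs not, crossed with predicted
#' target vs not.  The one-sided (enrichment) Fisher exact p-value is
#' the hypergeometric upper tail of the overlap count.
#'
#' @param negFlags logical per mRNA: negatively correlated with the
#'   miRNA.
#' @param targetFlags logical per mRNA (same order): predicted target of
#'   the miRNA.
#' @param alternative "greater" (one-sided enrichment, default) or
#'   "two.sided".
#' @return list: table (2x2 matrix), odds_ratio, p.
#' @examples
#' fisherEnrichment(c(TRUE, TRUE, FALSE, FALSE),
#'                  c(TRUE, TRUE, FALSE, FALSE))$p  # 1/6
#' @export
fisherEnrichment <- function(negFlags, targetFlags,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot2(length(negFlags) == length(targetFlags) && length(negFlags) > 0,
             "flags must be equal-length and nonempty")
  a <- sum(negFlags & targetFlags)
  b <- sum(negFlags & !targetFlags)
  c_ <- sum(!negFlags & targetFlags)
  d <- sum(!negFlags & !targetFlags)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(negative = c("yes", "no"),
                                target = c("yes", "no")))
  N <- a + b + c_ + d
  K <- a + c_                          # targets
  nNeg <- a + b
  if (alternative == "greater") {
    p <- stats::phyper(a - 1, K, N - K, nNeg, lower.tail = FALSE)
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  or <- (a * d) / max(b * c_, .Machine$double.xmin)
  list(table = tab, odds_ratio = or, p = p)
}

#' Per-miRNA enrichment records
#'
#' Runs \code{\link{fisherEnrichment}} for every miRNA over the mRNA
#' universe, using precomputed correlations.
#'
#' @param corTable output of \code{\link{correlateTargets}} for all
#'   (miRNA, mRNA) pairs in the universe.
#' @param targets data.frame: mirna_id, mrna_id of predicted targets.
#' @param universe character vector of mRNA IDs forming the contingency
#'   universe (default: all mRNAs in \code{corTable}).
#' @return data.frame: mirna_id, a, b, c, d, fisher_p.
#' @export
mirnaEnrichmentTable <- function(corTable, targets,
                                 universe = unique(corTable$mrna_id)) {
  out <- lapply(unique(corTable$mirna_id), function(mi) {
    sub <- corTable[corTable$mirna_id == mi & !corTable$excluded, ]
    sub <- sub[sub$mrna_id %in% universe, ]
    neg <- stats::setNames(sub$negative, sub$mrna_id)
    tg <- universe %in% targets$mrna_id[targets$mirna_id == mi]
    fl <- unname(neg[universe]); fl[is.na(fl)] <- FALSE
    fe <- fisherEnrichment(fl, tg)
    data.frame(mirna_id = mi, a = fe$table[1, 1], b = fe$table[1, 2],
               c = fe$table[2, 1], d = fe$table[2, 2], fisher_p = fe$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-criterion miRNA prioritization
#'
#' A miRNA is a candidate iff its Fisher enrichment p-value is strictly
#' below 0.05 AND the variance proportion explained by its target class
#' is strictly above 0.1.  Boundary values are excluded on both
#' criteria.  miRNAs lacking a fitted target-class h2 are skipped with a
#' warning.
#'
#' @param records data.frame with columns \code{mirna_id},
#'   \code{fisher_p}.
#' @param targetH2 named numeric: per-miRNA target-class variance
#'   proportion from the variance-partitioning stage.
#' @param pMax Fisher threshold (default 0.05, strict).
#' @param h2Min target-class h2 threshold (default 0.1, strict).
#' @return data.frame: mirna_id, fisher_p, h2_t, candidate.
#' @export
prioritizeMirnas <- function(records, targetH2, pMax = 0.05, h2Min = 0.1) {
  h2 <- targetH2[records$mirna_id]
  miss <- is.na(h2)
  if (any(miss))
    warning(sum(miss), " miRNA(s) without a target-class h2 skipped")
  out <- data.frame(mirna_id = records$mirna_id,
                    fisher_p = records$fisher_p, h2_t = unname(h2),
                    stringsAsFactors = FALSE)[!miss, ]
  out$candidate <- out$fisher_p < pMax & out$h2_t > h2Min
  out
}

#' Association between candidate and differentially expressed miRNAs
#'
#' 2x2 chi-square test (with continuity correction) of candidate status
#' against differential-expression status over a miRNA universe.  When
#' any expected cell count falls below 1 the Fisher exact test is
#' substituted and noted in the output.
#'
#' @param candidateSet,deSet character vectors (subsets of universe).
#' @param universe character vector of all tested miRNA IDs.
#' @return list: statistic (NA when exact), p, method, table.
#' @export
deOverlapTest <- function(candidateSet, deSet, universe) {
  stopifnot2(length(candidateSet) > 0, "empty candidate set")
  stopifnot2(all(candidateSet %in% universe) && all(deSet %in% universe),
             "sets must be subsets of the universe")
  cand <- universe %in% candidateSet
  de <- universe %in% deSet
  tab <- table(candidate = cand, de = de)
  if (!all(dim(tab) == c(2, 2)))
    stop("degenerate table: a margin is empty")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value, method = "fisher.exact",
         table = tab)
  } else {
    ct <- stats::chisq.test(tab, correct = TRUE)
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chisq", table = tab)
  }
}
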