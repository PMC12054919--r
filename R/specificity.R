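#' Preprocess an expression matrix for specificity testing
#'
#' log2(value + pseudo) transform followed by Z-score normalization
#' within each tissue.  The default scope \code{"tissue"} standardizes
#' each tissue's samples jointly (one mean and SD over all of that
#' tissue's values), which equalizes scale across tissue batches while
#' preserving between-gene differences -- the contrasts the specificity
#' t-statistic tests.  Scope \code{"gene"} standardizes every gene
#' separately within each tissue; it centres all tissue means to zero
#' and is only useful for diagnostics.  Tissues with a single sample
#' are excluded with a warning, since a within-tissue SD is undefined.
#'
#' @param expr genes x samples matrix of nonnegative expression values
#'   (e.g. FPKM).  Set \code{logTransform = FALSE} if already on log
#'   scale.
#' @param sampleMeta data.frame with columns \code{sample} and
#'   \code{tissue} matching \code{colnames(expr)}.
#' @param pseudo pseudo-count added before the log (default 1e-3).
#' @param logTransform apply log2(x + pseudo) first (default TRUE).
#' @param scope "tissue" (default) or "gene"; see above.
#' @return list: \code{expr} (normalized matrix), \code{sampleMeta}
#'   (possibly reduced).
#' @export
preprocessExpression <- function(expr, sampleMeta, pseudo = 1e-3,
                                 logTransform = TRUE,
                                 scope = c("tissue", "gene")) {
  scope <- match.arg(scope)
  stopifnot2(all(colnames(expr) %in% sampleMeta$sample),
             "sampleMeta must describe every expression column")
  meta <- sampleMeta[match(colnames(expr), sampleMeta$sample), ]
  if (logTransform) {
    stopifnot2(min(expr) >= 0, "expression values must be nonnegative")
    expr <- log2(expr + pseudo)
  }
  tab <- table(meta$tissue)
  solo <- names(tab)[tab < 2]
  if (length(solo)) {
    warning("tissue(s) with a single sample excluded: ",
            paste(solo, collapse = ", "))
    keep <- !(meta$tissue %in% solo)
    expr <- expr[, keep, drop = FALSE]
    meta <- meta[keep, ]
  }
  for (tt in unique(meta$tissue)) {
    j <- which(meta$tissue == tt)
    if (scope == "tissue") {
      vals <- expr[, j, drop = FALSE]
      s <- stats::sd(vals)
      if (s == 0) s <- Inf
      expr[, j] <- (vals - mean(vals)) / s
    } else {
      mu <- rowMeans(expr[, j, drop = FALSE])
      sd <- apply(expr[, j, drop = FALSE], 1, stats::sd)
      sd[sd == 0] <- Inf                     # constant gene -> all zeros
      expr[, j] <- (expr[, j, drop = FALSE] - mu) / sd
    }
  }
  list(expr = expr, sampleMeta = meta)
}

#' Tissue-specificity t-statistics
#'
#' Per gene, ordinary least squares of normalized expression on a design
#' whose first column codes +1 for target-tissue samples and -1 for
#' background samples, followed by an intercept and optional covariates;
#' the reported t-statistic is the coefficient of the tissue indicator
#' divided by its OLS standard error.  Samples whose tissue category is
#' in \code{excludedCategories} (e.g. related mammary tissues when
#' testing lactating mammary) are dropped before fitting, so the
#' background is strictly non-related tissue.  Genes with zero residual
#' variance get t = 0 and are flagged degenerate, keeping them out of
#' the top fraction.
#'
#' @param expr normalized genes x samples matrix (see
#'   \code{\link{preprocessExpression}}).
#' @param sampleMeta data.frame: sample, tissue, category, plus any
#'   covariate columns.
#' @param targetTissue tissue whose specificity is tested.
#' @param excludedCategories tissue categories removed from the
#'   comparison (the target's own samples are always kept).
#' @param covariates character vector of sampleMeta columns to adjust
#'   for (factors one-hot coded, numerics as-is); collinear columns are
#'   dropped with a warning.
#' @return data.frame: gene_id, t_statistic, coefficient, n_target,
#'   n_background, degenerate.
#' @export
tissueTStat <- function(expr, sampleMeta, targetTissue,
                        excludedCategories = character(),
                        covariates = character()) {
  meta <- sampleMeta[match(colnames(expr), sampleMeta$sample), ]
  isTarget <- meta$tissue == targetTissue
  drop <- !isTarget & (meta$category %in% excludedCategories)
  keep <- which(!drop)
  meta <- meta[keep, ]
  Y <- expr[, keep, drop = FALSE]
  isTarget <- isTarget[keep]
  stopifnot2(sum(isTarget) >= 2 && sum(!isTarget) >= 2,
             "need >= 2 target and >= 2 background samples")

  X <- cbind(tissue = ifelse(isTarget, 1, -1), intercept = 1)
  for (cv in covariates) {
    v <- meta[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, matrix(v, ncol = 1, dimnames = list(NULL, cv)))
    } else {
      v <- as.factor(v)
      tabv <- table(v)
      levels(v)[levels(v) %in% names(tabv)[tabv < 2]] <- ".other"
      if (nlevels(v) > 1) {
        mm <- stats::model.matrix(~ v)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
        X <- cbind(X, mm)
      }
    }
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropc <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("collinear covariate column(s) dropped: ",
            paste(dropc, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }

  n <- nrow(X); p <- ncol(X)
  B <- t(qr.coef(qrX, t(Y)))                  # genes x p
  fit <- t(qr.fitted(qrX, t(Y)))
  rss <- rowSums((Y - fit)^2)
  s2 <- rss / (n - p)
  XtXinv11 <- chol2inv(qr.R(qrX))[1, 1]
  se <- sqrt(s2 * XtXinv11)
  tval <- B[, 1] / se
  # zero residual variance (up to float noise) is degenerate: t pinned
  # to 0 so such genes can never enter the top fraction
  degen <- !is.finite(tval) |
    rss <= 1e-10 * pmax(rowSums(Y^2), .Machine$double.eps)
  tval[degen] <- 0

  data.frame(gene_id = rownames(Y), t_statistic = unname(tval),
             coefficient = unname(B[, 1]), n_target = sum(isTarget),
             n_background = sum(!isTarget), degenerate = unname(degen),
             stringsAsFactors = FALSE)
}

#' Call tissue-specific genes from the top fraction of t-statistics
#'
#' Genes whose t-statistic reaches the (1 - fraction) quantile cutoff;
#' ties at the cutoff are all included.  Degenerate genes (zero residual
#' variance) are ineligible.
#'
#' @param results data.frame from \code{\link{tissueTStat}}.
#' @param fraction top fraction to call specific (default 0.10).
#' @return character vector of specific gene IDs.
#' @export
topFraction <- function(results, fraction = 0.10) {
  stopifnot2(nrow(results) > 0, "no results")
  elig <- results[!results$degenerate, ]
  k <- ceiling(fraction * nrow(results))
  if (k >= nrow(elig)) return(elig$gene_id)
  cutoff <- sort(elig$t_statistic, decreasing = TRUE)[k]
  elig$gene_id[elig$t_statistic >= cutoff]
}

#' Correlation of t-statistics between two tissues
#'
#' Pearson correlation over the genes shared by both result tables.
#'
#' @param resA,resB data.frames from \code{\link{tissueTStat}}.
#' @return the correlation (numeric scalar).
#' @export
tstatCorrelation <- function(resA, resB) {
  shared <- intersect(resA$gene_id, resB$gene_id)
  stopifnot2(length(shared) >= 3, "need >= 3 shared genes")
  stats::cor(resA$t_statistic[match(shared, resA$gene_id)],
             resB$t_statistic[match(shared, resB$gene_id)])
}
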