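#' Simulate a multi-tissue expression panel with planted specific genes
#'
#' Generates a log-scale genes x samples matrix with N(0, 1) baseline
#' expression and a mean shift of \code{effectSize} for each tissue's
#' planted specific genes in that tissue's samples.  Sample covariates
#' (tissue, category, project, breed, sex, age) are emitted so the
#' specificity stage can be exercised with its full design matrix.
#'
#' @param nGenes number of genes.
#' @param tissueLayout named integer vector: tissue name -> number of
#'   samples (each >= 2).
#' @param nSpecificPerTissue planted tissue-specific genes per tissue
#'   (disjoint across tissues; total must not exceed \code{nGenes}).
#' @param effectSize mean log-expression shift of a planted gene in its
#'   tissue.
#' @param categoryOf optional named character vector mapping tissue ->
#'   tissue category (defaults to each tissue being its own category).
#' @param seed integer seed.
#' @return list: \code{expr} (genes x samples matrix, log scale),
#'   \code{sampleMeta} (data.frame: sample, tissue, category, project,
#'   breed, sex, age), \code{truth} (named list tissue -> planted gene
#'   IDs).
#' @examples
#' panel <- simExpressionPanel(200, c(mammary = 10, liver = 10),
#'                             nSpecificPerTissue = 5, effectSize = 3,
#'                             seed = 1)
#' dim(panel$expr)
#' @export
simExpressionPanel <- function(nGenes, tissueLayout, nSpecificPerTissue = 0,
                               effectSize = 0, categoryOf = NULL, seed = 1) {
  stopifnot2(all(tissueLayout >= 2), "every tissue needs >= 2 samples")
  stopifnot2(nSpecificPerTissue * length(tissueLayout) <= nGenes,
             "more planted specific genes than genes")
  tissues <- names(tissueLayout)
  if (is.null(categoryOf))
    categoryOf <- stats::setNames(tissues, tissues)

  withSeed(seed, {
    nS <- sum(tissueLayout)
    tissue <- rep(tissues, tissueLayout)
    sampleId <- sprintf("s%03d", seq_len(nS))
    genes <- sprintf("gene%05d", seq_len(nGenes))

    expr <- matrix(rnorm(nGenes * nS), nGenes, nS,
                   dimnames = list(genes, sampleId))

    truth <- list()
    used <- 0L
    for (tt in tissues) {
      idx <- if (nSpecificPerTissue > 0)
        seq.int(used + 1L, used + nSpecificPerTissue) else integer()
      used <- used + nSpecificPerTissue
      truth[[tt]] <- genes[idx]
      expr[idx, tissue == tt] <- expr[idx, tissue == tt] + effectSize
    }

    meta <- data.frame(
      sample = sampleId,
      tissue = tissue,
      category = unname(categoryOf[tissue]),
      project = sample(paste0("PRJ", 1:3), nS, replace = TRUE),
      breed = sample(c("holstein", "jersey"), nS, replace = TRUE),
      sex = sample(c("F", "M"), nS, replace = TRUE),
      age = round(runif(nS, 1, 8), 1),
      stringsAsFactors = FALSE)

    list(expr = expr, sampleMeta = meta, truth = truth)
  })
}
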