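#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenotypeMatrix: individuals-by-variants dosage panel
#'
#' Holds biallelic dosages in \{0, 1, 2\} (with \code{NA} for missing calls)
#' for a set of individuals, together with per-variant metadata as a
#' \link[GenomicRanges]{GRanges} (width-1 ranges; metadata columns
#' \code{id}, \code{ref}, \code{alt}).  Positions are stored 1-based as is
#' native to \code{GRanges}; BED input/output converts at the boundary.
#'
#' @slot dosages numeric matrix, individuals x variants; rownames are
#'   sample IDs, colnames are variant IDs.
#' @slot variants \code{GRanges} of length \code{ncol(dosages)}, sorted by
#'   (chromosome, position), with \code{seqlengths} set when known.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", variants = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  v <- object@variants
  if (length(v) != ncol(d))
    msg <- c(msg, "length(variants) must equal ncol(dosages)")
  if (is.null(rownames(d)))
    msg <- c(msg, "dosages must have sample IDs as rownames")
  if (is.null(v$id) || anyDuplicated(v$id))
    msg <- c(msg, "variants must carry unique 'id' metadata")
  if (!is.null(colnames(d)) && !identical(colnames(d), as.character(v$id)))
    msg <- c(msg, "colnames(dosages) must match variants$id")
  ok <- d[!is.na(d)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(v) > 1) {
    o <- order(as.integer(seqnames(v)), start(v))
    if (!identical(o, seq_along(v)))
      msg <- c(msg, "variants must be sorted by (chromosome, position)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages individuals x variants matrix of dosages in \{0,1,2\}
#'   (\code{NA} allowed); rownames are sample IDs.
#' @param variants \code{GRanges} with metadata column \code{id} (unique
#'   variant IDs) and optionally \code{ref}, \code{alt}.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(5, 9), width = 1),
#'                              id = c("v1", "v2"))
#' gm <- GenotypeMatrix(matrix(c(0, 1, 2, 1), 2, 2,
#'                             dimnames = list(c("s1", "s2"), c("v1", "v2"))),
#'                      gr)
#' nVariants(gm)
#' @export
GenotypeMatrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "G"
  o <- order(as.integer(seqnames(variants)), start(variants))
  variants <- variants[o]
  dosages <- dosages[, o, drop = FALSE]
  colnames(dosages) <- as.character(variants$id)
  new("GenotypeMatrix", dosages = dosages, variants = variants)
}

#' @describeIn GenotypeMatrix dosage matrix (individuals x variants)
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn GenotypeMatrix variant metadata as GRanges
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x) x@variants)

#' @describeIn GenotypeMatrix variant IDs
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @export
setMethod("variantIds", "GenotypeMatrix",
          function(x) as.character(x@variants$id))

#' @describeIn GenotypeMatrix sample IDs
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @describeIn GenotypeMatrix number of variants
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))

#' @describeIn GenotypeMatrix number of individuals
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))

#' Subset a GenotypeMatrix
#'
#' `x[i, j]` keeps individuals `i` and variants `j` (IDs, indices or
#' logical masks).
#' @param x a \code{GenotypeMatrix}
#' @param i,j sample / variant selectors
#' @param ... ignored
#' @param drop ignored (always \code{FALSE})
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  if (is.character(j)) j <- match(j, x@variants$id)
  d <- x@dosages[i, j, drop = FALSE]
  GenotypeMatrix(d, x@variants[j])
})

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@variants
  cat("GenotypeMatrix:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants on",
      length(unique(as.character(seqnames(v)))), "chromosome(s)\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missing rate %.3f\n", miss))
})

#' GRM: genomic relationship matrix
#'
#' VanRaden (method 1) genomic relationships among individuals:
#' \eqn{G = ZZ'/(2\sum_j p_j(1-p_j))} with \eqn{Z} the column-centred
#' dosage matrix.
#'
#' @slot mat symmetric individuals x individuals matrix, dimnames = sample
#'   IDs.
#' @slot nVariantsUsed number of (polymorphic) variants in the sum.
#' @aliases GRM-class
#' @export
setClass("GRM", representation(mat = "matrix", nVariantsUsed = "integer"))

setValidity("GRM", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    return("matrix must be symmetric")
  if (is.null(rownames(m))) return("matrix must carry sample IDs")
  TRUE
})

#' @describeIn GRM the relationship matrix itself
#' @param x,object a \code{GRM}
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @export
setMethod("grmMatrix", "GRM", function(x) x@mat)

#' @describeIn GRM number of variants used in construction
#' @export
setGeneric("nVariantsUsed", function(x) standardGeneric("nVariantsUsed"))

#' @export
setMethod("nVariantsUsed", "GRM", function(x) x@nVariantsUsed)

#' @export
setMethod("sampleIds", "GRM", function(x) rownames(x@mat))

setMethod("show", "GRM", function(object) {
  n <- nrow(object@mat)
  cat("GRM:", n, "individuals,", object@nVariantsUsed, "variants;",
      sprintf("mean diagonal %.3f\n", mean(diag(object@mat))))
})

#' FunctionalClassMap: named variant subsets
#'
#' Maps functional class names to sets of variant IDs, plus the designated
#' \code{"other"} class holding the complement of the union of all
#' functional classes.  Classes may overlap; overlap resolution is applied
#' only when fitting (see \code{\link{partitionMulti}}).
#'
#' @slot classes named list of character vectors of variant IDs (excluding
#'   \code{"other"}).
#' @slot other character vector: variant IDs in no functional class.
#' @slot provenance list describing how each class was built (intervals +
#'   flank, or explicit list).
#' @aliases FunctionalClassMap-class
#' @export
setClass("FunctionalClassMap",
  representation(classes = "list", other = "character", provenance = "list"))

setValidity("FunctionalClassMap", function(object) {
  if (length(object@classes) && is.null(names(object@classes)))
    return("classes must be named")
  if ("other" %in% names(object@classes))
    return("'other' is reserved for the complement class")
  TRUE
})

#' @describeIn FunctionalClassMap class name -> variant IDs (the
#'   \code{"other"} complement class included)
#' @param x,object a \code{FunctionalClassMap}
#' @export
setGeneric("classMembers", function(x) standardGeneric("classMembers"))

#' @export
setMethod("classMembers", "FunctionalClassMap", function(x)
  c(x@classes, list(other = x@other)))

#' @describeIn FunctionalClassMap functional class names (without
#'   \code{"other"})
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @export
setMethod("classNames", "FunctionalClassMap", function(x) names(x@classes))

setMethod("show", "FunctionalClassMap", function(object) {
  cat("FunctionalClassMap with", length(object@classes),
      "functional class(es):\n")
  for (nm in names(object@classes))
    cat(sprintf("  %-20s %d variants\n", nm, length(object@classes[[nm]])))
  cat(sprintf("  %-20s %d variants\n", "other", length(object@other)))
})

#' VarCompFit: multi-GRM REML variance component fit
#'
#' @slot sigma2 named numeric: per-component genetic variance estimates.
#' @slot sigma2e residual variance.
#' @slot se named numeric: standard errors (components then "residual"),
#'   from the inverse average-information matrix.
#' @slot seProp named numeric: delta-method standard errors of the
#'   variance proportions.
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot converged logical.
#' @slot nIter number of iterations used.
#' @slot n number of individuals.
#' @aliases VarCompFit-class
#' @export
setClass("VarCompFit",
  representation(sigma2 = "numeric", sigma2e = "numeric", se = "numeric",
                 seProp = "numeric", loglik = "numeric",
                 converged = "logical", nIter = "integer", n = "integer"))

#' @describeIn VarCompFit per-component variance proportions
#'   \eqn{h^2_f = \sigma^2_f/\sigma^2_P}
#' @param x,object a \code{VarCompFit}
#' @export
setGeneric("varProportions", function(x) standardGeneric("varProportions"))

#' @export
setMethod("varProportions", "VarCompFit", function(x) {
  tot <- sum(x@sigma2) + x@sigma2e
  x@sigma2 / tot
})

#' @describeIn VarCompFit total genetic proportion (sum over components)
#' @export
setGeneric("h2All", function(x) standardGeneric("h2All"))

#' @export
setMethod("h2All", "VarCompFit", function(x) sum(varProportions(x)))

#' @describeIn VarCompFit named variance estimates including residual
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @export
setMethod("varComponents", "VarCompFit", function(x)
  c(x@sigma2, residual = x@sigma2e))

setMethod("show", "VarCompFit", function(object) {
  p <- varProportions(object)
  cat("VarCompFit (", if (object@converged) "converged" else "NOT converged",
      ", ", object@nIter, " iterations, n = ", object@n, ")\n", sep = "")
  for (nm in names(object@sigma2))
    cat(sprintf("  %-20s sigma2 = %.4g  h2 = %.4f (se %.4f)\n", nm,
                object@sigma2[nm], p[nm],
                if (nm %in% names(object@seProp)) object@seProp[nm] else NA))
  cat(sprintf("  residual             sigma2 = %.4g\n", object@sigma2e))
  cat(sprintf("  h2(all) = %.4f   logLik = %.3f\n", sum(p), object@loglik))
})

#' PredictionFit: genomic prediction result
#'
#' @slot model one of "GBLUP", "MultiBLUP", "BayesR", "BayesRC".
#' @slot gebv named numeric: genomic value per individual (all animals,
#'   reference and validation).
#' @slot hyper list of estimated variance components / posterior means.
#' @slot mcmc list(nIter, burnIn, seed) for the Bayes models, empty
#'   otherwise.
#' @slot piPosterior posterior mean mixture proportions: matrix with one
#'   row per annotation class (single row for BayesR), or NULL.
#' @aliases PredictionFit-class
#' @export
setClass("PredictionFit",
  representation(model = "character", gebv = "numeric", hyper = "list",
                 mcmc = "list", piPosterior = "matrixOrNULL"))

#' @describeIn PredictionFit genomic estimated breeding values
#' @param x,object a \code{PredictionFit}
#' @export
setGeneric("gebv", function(x) standardGeneric("gebv"))

#' @export
setMethod("gebv", "PredictionFit", function(x) x@gebv)

setMethod("show", "PredictionFit", function(object) {
  cat("PredictionFit:", object@model, "for", length(object@gebv),
      "individuals\n")
  if (length(object@mcmc))
    cat("  MCMC:", object@mcmc$nIter, "iterations,", object@mcmc$burnIn,
        "burn-in\n")
  if (!is.null(object@piPosterior)) {
    cat("  posterior mixture proportions:\n")
    print(round(object@piPosterior, 4))
  }
})
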