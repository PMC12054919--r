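#' Simulate a biallelic genotype panel
#'
#' Draws per-variant alternate-allele frequencies uniformly within
#' \code{mafRange} and dosages as Binomial(2, p) per individual, i.e.
#' unlinked variants in Hardy-Weinberg proportions.  Variant positions are
#' placed uniformly (without replacement) along the given chromosomes and
#' sorted.
#'
#' @param nIndividuals number of individuals (>= 2).
#' @param nVariants total number of variants (>= 1), split across
#'   chromosomes proportionally to their lengths.
#' @param chromLengths named or unnamed numeric vector of chromosome
#'   lengths in bp (all > 0).  Unnamed vectors get names "chr1", ...
#' @param mafRange length-2 vector in (0, 0.5]: bounds for the uniform
#'   allele-frequency draw.
#' @param seed integer seed; the draw is bit-reproducible given the same
#'   arguments and seed.
#' @return A \linkS4class{GenotypeMatrix} with \code{seqlengths} set.
#' @examples
#' gm <- simGenotypes(10, 20, chromLengths = c(1e5, 5e4),
#'                    mafRange = c(0.1, 0.5), seed = 1)
#' dim(dosages(gm))
#' @export
simGenotypes <- function(nIndividuals, nVariants,
                         chromLengths = c(chr1 = 1e6),
                         mafRange = c(0.05, 0.5), seed = 1) {
  stopifnot2(nIndividuals >= 2, "nIndividuals must be >= 2")
  stopifnot2(nVariants >= 1, "nVariants must be >= 1")
  stopifnot2(length(mafRange) == 2 && mafRange[1] > 0 &&
             mafRange[2] <= 0.5 && mafRange[1] <= mafRange[2],
             "mafRange must lie within (0, 0.5]")
  stopifnot2(all(chromLengths > 0), "chromLengths must all be positive")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  stopifnot2(sum(chromLengths) >= nVariants,
             "genome too short for the requested variant count")

  withSeed(seed, {
    # variants per chromosome ~ proportional to length
    cum <- round(cumsum(chromLengths) / sum(chromLengths) * nVariants)
    cum[length(cum)] <- nVariants
    mPer <- diff(c(0, cum))
    names(mPer) <- names(chromLengths)

    chrom <- rep(names(chromLengths), mPer)
    pos <- unlist(lapply(seq_along(chromLengths), function(i) {
      sort(sample.int(chromLengths[i], mPer[i]))
    }), use.names = FALSE)

    p <- runif(nVariants, mafRange[1], mafRange[2])
    d <- matrix(rbinom(nIndividuals * nVariants, 2L, rep(p, each = nIndividuals)),
                nrow = nIndividuals)
    rownames(d) <- sprintf("ind%04d", seq_len(nIndividuals))

    gr <- GRanges(chrom, IRanges(pos, width = 1),
                  seqlengths = chromLengths,
                  id = sprintf("var%06d", seq_len(nVariants)),
                  ref = "A", alt = "G")
    GenotypeMatrix(d, gr)
  })
}
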