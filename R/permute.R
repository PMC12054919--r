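#' Genome layout for circular coordinates
#'
#' Concatenates the autosomes into a single circle of length
#' \eqn{L = \sum_i l_i}.  A site at position \eqn{B} (1-based) on the
#' \eqn{N}-th chromosome has continuous position
#' \eqn{\sum_{i=1}^{N-1} l_i + B}.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp,
#'   in genome order (all > 0).
#' @return an object of class \code{"GenomeLayout"} (list: lengths,
#'   offsets, total).
#' @examples
#' lay <- genomeLayout(c(chr1 = 100, chr2 = 200))
#' toContinuous("chr2", 50, lay)  # 150
#' @export
genomeLayout <- function(chromLengths) {
  stopifnot2(all(chromLengths > 0), "chromosome lengths must be positive")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  structure(list(lengths = chromLengths,
                 offsets = c(0, cumsum(chromLengths))[seq_along(chromLengths)],
                 total = sum(chromLengths)),
            class = "GenomeLayout")
}

#' @describeIn genomeLayout map (chrom, pos) to continuous position
#' @param chrom chromosome names
#' @param pos 1-based positions, each within its chromosome's length
#' @param layout a \code{GenomeLayout}
#' @export
toContinuous <- function(chrom, pos, layout) {
  i <- match(chrom, names(layout$lengths))
  stopifnot2(!anyNA(i), "unknown chromosome name")
  stopifnot2(all(pos >= 1 & pos <= layout$lengths[i]),
             "position beyond chromosome length")
  unname(layout$offsets[i] + pos)
}

#' @describeIn genomeLayout map continuous positions back to (chrom, pos)
#' @param cont continuous positions in [1, total]
#' @export
fromContinuous <- function(cont, layout) {
  stopifnot2(all(cont >= 1 & cont <= layout$total),
             "continuous position out of range")
  i <- findInterval(cont - 1, c(layout$offsets, layout$total),
                    rightmost.closed = FALSE)
  data.frame(chrom = names(layout$lengths)[i],
             pos = unname(cont - layout$offsets[i]),
             stringsAsFactors = FALSE)
}

#' Circular genome shift of a site set
#'
#' Advances every site by a common offset \code{R} along the
#' concatenated-genome circle; positions running past the end wrap
#' around by subtracting the total length.  The multiset of circular
#' inter-site distances is exactly preserved, so the shifted set is a
#' position-matched null that keeps the sites' clustering structure.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos}
#'   (1-based), or a width-1 \code{GRanges}.
#' @param R shift in bp, in [1, total genome length].
#' @param layout a \code{GenomeLayout}.
#' @return data.frame: chrom, pos of the shifted sites (input order).
#' @export
genomeShift <- function(sites, R, layout) {
  if (is(sites, "GRanges"))
    sites <- data.frame(chrom = as.character(seqnames(sites)),
                        pos = start(sites), stringsAsFactors = FALSE)
  stopifnot2(R >= 1 && R <= layout$total, "R must lie in [1, L]")
  cont <- toContinuous(sites$chrom, sites$pos, layout) + R
  wrap <- cont > layout$total
  cont[wrap] <- cont[wrap] - layout$total
  fromContinuous(cont, layout)
}

#' Circular-permutation null for class-level variance
#'
#' For each permutation a single genome-wide shift \code{R} is drawn
#' uniformly on [1, L]; the observed sites are shifted, the flanking
#' windows are re-expanded around the shifted sites, the two-GRM
#' partition (class vs rest) is refitted, and the class variance
#' proportion is recorded.  The empirical p-value uses add-one
#' smoothing, \eqn{p = (1 + \#\{null \ge observed\})/(nPerm + 1)}, and is
#' therefore never zero.
#'
#' @param y phenotypes (see \code{\link{fitREML}}).
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param sites width-1 \code{GRanges} (or data.frame chrom/pos) of the
#'   observed sites.
#' @param flankBp flanking window used to turn sites into a variant
#'   class.
#' @param layout a \code{GenomeLayout} covering the panel's chromosomes.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed; permutation \code{i} uses an independent
#'   child stream so results are reproducible regardless of evaluation
#'   order.
#' @return list: \code{observed} (class h2), \code{null} (numeric vector
#'   of length nPerm), \code{nullMean}, \code{nullSd}, \code{pEmpirical},
#'   \code{shifts} (the R values).
#' @export
permutationNull <- function(y, geno, sites, flankBp, layout, nPerm = 100,
                            seed = 1) {
  stopifnot2(nPerm >= 1, "nPerm must be >= 1")
  if (is(sites, "GRanges"))
    sites <- data.frame(chrom = as.character(seqnames(sites)),
                        pos = start(sites), stringsAsFactors = FALSE)

  h2Of <- function(siteDf) {
    gr <- GRanges(siteDf$chrom, IRanges(siteDf$pos, width = 1))
    cm <- classMapFromSites(geno, gr, flankBp)
    if (length(classMembers(cm)$sites) == 0 ||
        length(classMembers(cm)$other) == 0) return(NA_real_)
    fit <- partitionTwo(y, geno, cm, "sites")
    unname(varProportions(fit)["sites"])
  }

  observed <- h2Of(sites)
  stopifnot2(is.finite(observed),
             "observed class is empty or covers the whole panel")

  null <- numeric(nPerm)
  shifts <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    withSeed(childSeed(seed, i), {
      R <- sample.int(layout$total, 1)
      shifts[i] <- R
      null[i] <- h2Of(genomeShift(sites, R, layout))
    })
  }
  ok <- is.finite(null)
  p <- (1 + sum(null[ok] >= observed)) / (sum(ok) + 1)
  list(observed = observed, null = null, nullMean = mean(null[ok]),
       nullSd = stats::sd(null[ok]), pEmpirical = p, shifts = shifts)
}
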