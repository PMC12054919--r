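#' Simulate reads with planted A-to-G RNA editing
#'
#' Builds a random DNA reference, plants editing sites (reference base
#' forced to A) in clusters, and tiles the reference with fixed-length
#' reads at the stated depth.  Each read shows G at an overlapped planted
#' site with marginal probability equal to that site's editing level,
#' and carries independent uniform per-base sequencing errors.
#'
#' Editing events within one read are co-edited through a shared
#' per-read propensity (the \code{processivity} parameter): a read
#' either derives from an ADAR-processed molecule, in which case each
#' overlapped site is edited with probability ~\code{processivity}, or
#' shows no editing at all.  The marginal per-site editing level is
#' preserved exactly; setting \code{processivity = 1} recovers a
#' molecule that is either fully edited or untouched, while levels
#' above \code{processivity} fall back to independent editing at that
#' site.
#'
#' @param refLength reference length in bp.
#' @param nSites number of planted editing sites.
#' @param levels editing level per site in [0, 1]; recycled.
#' @param depth mean read depth.
#' @param readLength read length in bp.
#' @param errorRate per-base sequencing error probability.
#' @param sitesPerCluster planted sites per cluster (default 6).
#' @param siteSpacing bp between consecutive sites within a cluster
#'   (default 5).
#' @param processivity conditional per-site editing probability on an
#'   ADAR-processed molecule, in (0, 1] (default 0.85).
#' @param qualityPhred constant Phred base quality emitted (default 37).
#' @param seed integer seed.
#' @return list: \code{reference} (character, one sequence named "ref"),
#'   \code{reads} (data.frame: read_id, chrom, pos (1-based start), seq,
#'   qual), \code{truth} (data.frame: chrom, pos, level).
#' @examples
#' fx <- simEditedReads(2000, nSites = 6, levels = 0.5, depth = 20,
#'                      readLength = 50, errorRate = 0, seed = 1)
#' nrow(fx$reads)
#' @export
simEditedReads <- function(refLength, nSites, levels, depth = 50,
                           readLength = 50, errorRate = 0.001,
                           sitesPerCluster = 6, siteSpacing = 5,
                           processivity = 0.85, qualityPhred = 37,
                           seed = 1) {
  stopifnot2(all(levels >= 0 & levels <= 1), "levels must lie in [0, 1]")
  stopifnot2(processivity > 0 && processivity <= 1,
             "processivity must lie in (0, 1]")
  stopifnot2(readLength <= refLength, "reads longer than reference")
  levels <- rep_len(levels, nSites)

  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, refLength, replace = TRUE)

    # cluster layout: evenly spaced cluster starts, sites every
    # siteSpacing bp within a cluster
    nClust <- ceiling(nSites / sitesPerCluster)
    clustSpan <- (sitesPerCluster - 1) * siteSpacing + 1
    pad <- readLength
    avail <- refLength - 2 * pad - clustSpan
    stopifnot2(nSites == 0 || avail > 0,
               "site placement impossible: reference too short")
    starts <- if (nClust > 1)
      round(seq(pad + 1, pad + 1 + avail, length.out = nClust))
    else pad + 1
    sitePos <- integer(0)
    for (cs in starts) {
      k <- min(sitesPerCluster, nSites - length(sitePos))
      sitePos <- c(sitePos, cs + siteSpacing * seq_len(k) - siteSpacing)
      if (length(sitePos) >= nSites) break
    }
    ref[sitePos] <- "A"                      # editing only occurs at A

    nReads <- max(1L, round(refLength * depth / readLength))
    step <- (refLength - readLength) / max(1L, nReads - 1L)
    startsR <- as.integer(pmax(1, pmin(refLength - readLength + 1,
                                       round(1 + step * (seq_len(nReads) - 1)))))

    qual <- paste(rep(rawToChar(as.raw(qualityPhred + 33L)), readLength),
                  collapse = "")
    seqs <- character(nReads)
    for (r in seq_len(nReads)) {
      s <- startsR[r]
      rd <- ref[s:(s + readLength - 1L)]
      ov <- which(sitePos >= s & sitePos <= s + readLength - 1L)
      if (length(ov)) {
        # shared propensity z: edited iff z below level/thin (molecule
        # processed) and an independent thinning draw below thin, with
        # thin = processivity capped from below by the site level, so
        # the marginal editing probability is exactly the level
        z <- stats::runif(1)
        thin <- pmax(processivity, levels[ov])
        ed <- z < levels[ov] / thin & stats::runif(length(ov)) < thin
        rd[sitePos[ov[ed]] - s + 1L] <- "G"
      }
      if (errorRate > 0) {
        err <- which(stats::runif(readLength) < errorRate)
        for (i in err)
          rd[i] <- sample(setdiff(bases, rd[i]), 1L)
      }
      seqs[r] <- paste(rd, collapse = "")
    }

    list(reference = stats::setNames(paste(ref, collapse = ""), "ref"),
         reads = data.frame(read_id = sprintf("read%05d", seq_len(nReads)),
                            chrom = "ref", pos = startsR, seq = seqs,
                            qual = qual, stringsAsFactors = FALSE),
         truth = data.frame(chrom = "ref", pos = sitePos,
                            level = levels[seq_along(sitePos)],
                            stringsAsFactors = FALSE))
  })
}
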