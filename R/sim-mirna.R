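#' Simulate a miRNA / mRNA expression system with planted regulators
#'
#' A stated fraction of miRNAs are "true regulators": a fraction of their
#' listed predicted targets is generated anti-correlated with the miRNA
#' at strength \code{corrStrength} (expected Pearson correlation of
#' \eqn{-corrStrength}); all other expression is independent noise.
#' Predicted-target lists always have \code{targetsPerMirna} entries per
#' miRNA, whether or not the miRNA truly regulates them, mimicking the
#' high false-positive rate of sequence-based target prediction.
#'
#' @param nMirna,nMrna numbers of miRNAs and mRNAs.
#' @param targetsPerMirna predicted targets per miRNA (<= nMrna).
#' @param fracTrueRegulators fraction of miRNAs that truly repress a
#'   subset of their targets.
#' @param fracTrueTargets fraction of a true regulator's listed targets
#'   that are really repressed (default 0.5).
#' @param corrStrength target anti-correlation magnitude in [0, 1).
#' @param nSamples number of matched samples.
#' @param seed integer seed.
#' @return list: \code{mirnaExpr} (miRNAs x samples), \code{mrnaExpr}
#'   (mRNAs x samples), \code{targets} (data.frame mirna_id, mrna_id),
#'   \code{truth} (list: \code{regulators} = character vector of true
#'   regulator miRNA IDs; \code{truePairs} = data.frame of truly
#'   repressed pairs).
#' @export
simMirnaSystem <- function(nMirna, nMrna, targetsPerMirna,
                           fracTrueRegulators = 0.3, fracTrueTargets = 0.5,
                           corrStrength = 0.8, nSamples = 100, seed = 1) {
  stopifnot2(targetsPerMirna <= nMrna, "targetsPerMirna must be <= nMrna")
  stopifnot2(corrStrength >= 0 && corrStrength < 1,
             "corrStrength must lie in [0, 1)")

  withSeed(seed, {
    mirnaIds <- sprintf("mir%03d", seq_len(nMirna))
    mrnaIds <- sprintf("mrna%05d", seq_len(nMrna))

    mirnaExpr <- matrix(rnorm(nMirna * nSamples), nMirna, nSamples,
                        dimnames = list(mirnaIds, NULL))
    mrnaExpr <- matrix(rnorm(nMrna * nSamples), nMrna, nSamples,
                       dimnames = list(mrnaIds, NULL))

    nReg <- round(fracTrueRegulators * nMirna)
    regulators <- if (nReg > 0) mirnaIds[seq_len(nReg)] else character()

    targets <- do.call(rbind, lapply(mirnaIds, function(mi) {
      data.frame(mirna_id = mi,
                 mrna_id = sample(mrnaIds, targetsPerMirna),
                 stringsAsFactors = FALSE)
    }))

    truePairs <- data.frame(mirna_id = character(), mrna_id = character(),
                            stringsAsFactors = FALSE)
    if (corrStrength > 0 && length(regulators)) {
      for (mi in regulators) {
        tg <- targets$mrna_id[targets$mirna_id == mi]
        nTrue <- round(fracTrueTargets * length(tg))
        if (nTrue == 0) next
        tg <- tg[seq_len(nTrue)]
        x <- mirnaExpr[mi, ]
        noise <- sqrt(1 - corrStrength^2)
        for (tt in tg)
          mrnaExpr[tt, ] <- -corrStrength * x + noise * rnorm(nSamples)
        truePairs <- rbind(truePairs,
                           data.frame(mirna_id = mi, mrna_id = tg,
                                      stringsAsFactors = FALSE))
      }
    }

    list(mirnaExpr = mirnaExpr, mrnaExpr = mrnaExpr, targets = targets,
         truth = list(regulators = regulators, truePairs = truePairs))
  })
}
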