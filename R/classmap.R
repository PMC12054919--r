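#' Build a functional-class map from intervals and/or explicit ID lists
#'
#' Interval-defined classes contain every variant whose position falls
#' within an interval extended by the class's flanking window (clipped at
#' chromosome bounds); explicit classes are given as variant-ID vectors.
#' The designated \code{"other"} class is the complement of the union of
#' all functional classes.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param intervalSets named list of \link[GenomicRanges]{GRanges}
#'   (1-based, closed; use \code{readClassBed} for BED input).
#' @param flankBp flanking window in bp: a single number, or a named
#'   vector/list keyed by class name (default 0).
#' @param explicitSets named list of character vectors of variant IDs.
#' @return a \linkS4class{FunctionalClassMap}.
#' @examples
#' gm <- simGenotypes(10, 50, chromLengths = c(chr1 = 1e5), seed = 1)
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e4))
#' cm <- buildClassMap(gm, intervalSets = list(left = gr), flankBp = 0)
#' classNames(cm)
#' @export
buildClassMap <- function(geno, intervalSets = list(), flankBp = 0,
                          explicitSets = list()) {
  v <- variantRanges(geno)
  ids <- as.character(v$id)
  chromOk <- unique(as.character(seqnames(v)))

  flankOf <- function(nm) {
    if (length(flankBp) == 1 && is.null(names(flankBp))) return(as.numeric(flankBp))
    f <- unlist(flankBp)[nm]
    if (is.na(f)) 0 else as.numeric(f)
  }

  classes <- list()
  provenance <- list()
  for (nm in names(intervalSets)) {
    gr <- intervalSets[[nm]]
    bad <- setdiff(unique(as.character(seqnames(gr))), chromOk)
    if (length(bad))
      stop("unknown chromosome name(s) in intervals for class '", nm,
           "': ", paste(bad, collapse = ", "))
    fl <- flankOf(nm)
    gre <- GRanges(seqnames(gr),
                   IRanges(pmax(1, start(gr) - fl), end(gr) + fl))
    hit <- IRanges::overlapsAny(v, gre)
    classes[[nm]] <- ids[hit]
    provenance[[nm]] <- list(type = "intervals", n_intervals = length(gr),
                             flank_bp = fl)
  }
  for (nm in names(explicitSets)) {
    miss <- setdiff(explicitSets[[nm]], ids)
    stopifnot2(length(miss) == 0,
               paste0("class '", nm, "' references unknown variant IDs"))
    classes[[nm]] <- explicitSets[[nm]]
    provenance[[nm]] <- list(type = "explicit",
                             n = length(explicitSets[[nm]]))
  }

  other <- setdiff(ids, unique(unlist(classes, use.names = FALSE)))
  new("FunctionalClassMap", classes = classes, other = other,
      provenance = provenance)
}

#' Class map around a set of genomic sites
#'
#' Convenience wrapper used by the permutation null: a single class made
#' of all variants within \code{flankBp} of any site.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param sites \code{GRanges} (width-1) of site positions.
#' @param flankBp symmetric flanking window in bp.
#' @param name class name (default "sites").
#' @return a \linkS4class{FunctionalClassMap} with one functional class.
#' @export
classMapFromSites <- function(geno, sites, flankBp, name = "sites") {
  sets <- list(sites)
  names(sets) <- name
  fl <- list(flankBp)
  names(fl) <- name
  buildClassMap(geno, intervalSets = sets, flankBp = fl)
}
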