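#' Genotype panel TSV input/output
#'
#' Plain-text variants-by-samples layout: columns \code{chrom},
#' \code{pos} (1-based), \code{id}, \code{ref}, \code{alt}, then one
#' dosage column per sample.  Missing dosages are written as \code{NA}.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path file path.
#' @return \code{readGenotypesTSV} returns a
#'   \linkS4class{GenotypeMatrix}; the writer returns \code{path}
#'   invisibly.
#' @export
writeGenotypesTSV <- function(geno, path) {
  v <- variantRanges(geno)
  df <- data.frame(chrom = as.character(seqnames(v)), pos = start(v),
                   id = v$id, ref = v$ref, alt = v$alt,
                   t(dosages(geno)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTSV
#' @export
readGenotypesTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- c("chrom", "pos", "id", "ref", "alt")
  stopifnot2(all(meta %in% names(df)), "malformed genotype TSV")
  samp <- setdiff(names(df), meta)
  d <- t(as.matrix(df[samp]))
  rownames(d) <- samp
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1), id = df$id,
                ref = df$ref, alt = df$alt)
  GenotypeMatrix(d, gr)
}

#' Phenotype table TSV input/output
#'
#' Columns: \code{animal_id}, \code{dpta}, \code{reliability}, plus any
#' extra columns (e.g. \code{birth_year}) passed through unchanged.
#'
#' @param pheno data.frame with at least animal_id, dpta, reliability.
#' @param path file path.
#' @export
writePhenotypesTSV <- function(pheno, path) {
  stopifnot2(all(c("animal_id", "dpta", "reliability") %in% names(pheno)),
             "phenotype table needs animal_id, dpta, reliability")
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypesTSV
#' @export
readPhenotypesTSV <- function(path) {
  df <- utils::read.delim(path)
  stopifnot2(all(c("animal_id", "dpta", "reliability") %in% names(df)),
             "malformed phenotype TSV")
  df
}

#' Read BED intervals as GRanges
#'
#' BED is 0-based half-open; the returned \code{GRanges} is 1-based
#' closed, as used throughout the package.
#'
#' @param path BED3(+name) file path.
#' @return a \code{GRanges}.
#' @export
readClassBed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE))
    return(rtracklayer::import(path, format = "BED"))
  df <- utils::read.delim(path, header = FALSE)
  GRanges(df[[1]], IRanges(df[[2]] + 1, df[[3]]))
}

#' Write width-1 sites (or intervals) as BED
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @export
writeClassBed <- function(gr, path) {
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1, end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read fixtures in SAM-lite TSV form
#'
#' Columns: read_id, chrom, pos (1-based), seq, qual — the ungapped
#' subset of SAM this package's editing pipeline consumes.
#'
#' @param reads data.frame as produced by \code{\link{simEditedReads}}.
#' @param path file path.
#' @export
writeReadsTSV <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeReadsTSV
#' @export
readReadsTSV <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    read_id = "character", chrom = "character", pos = "integer",
    seq = "character", qual = "character"))
  stopifnot2(all(c("read_id", "chrom", "pos", "seq", "qual") %in%
                   names(df)), "malformed reads TSV")
  df
}

#' Expression matrix TSV input/output
#'
#' Genes x samples layout: first column \code{gene_id}, remaining
#' columns one per sample (header = sample IDs).
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path file path.
#' @export
writeExpressionTSV <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot2("gene_id" %in% names(df), "malformed expression TSV")
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  m
}

#' miRNA target-list TSV input/output
#'
#' Two columns: \code{mirna_id}, \code{mrna_id}, one row per predicted
#' pair.
#'
#' @param targets data.frame with mirna_id and mrna_id columns.
#' @param path file path.
#' @export
writeTargetsTSV <- function(targets, path) {
  utils::write.table(targets[c("mirna_id", "mrna_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTargetsTSV
#' @export
readTargetsTSV <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot2(all(c("mirna_id", "mrna_id") %in% names(df)),
             "malformed target TSV")
  df
}

#' Write a variance-component fit report as TSV
#'
#' One row per component: name, variance, proportion, standard errors,
#' and (when class counts are supplied) the enrichment odds ratio.
#'
#' @param fit a \linkS4class{VarCompFit}.
#' @param path file path.
#' @param counts optional named variant counts for \code{enrichment}.
#' @param nTotal optional total variant count.
#' @export
writeFitTSV <- function(fit, path, counts = NULL, nTotal = NULL) {
  prop <- varProportions(fit)
  df <- data.frame(component = names(fit@sigma2),
                   sigma2 = unname(fit@sigma2),
                   h2_f = unname(prop),
                   se_sigma2 = unname(fit@se[names(fit@sigma2)]),
                   se_h2 = unname(fit@seProp))
  if (!is.null(counts)) {
    if (is.null(nTotal)) nTotal <- sum(counts)
    enr <- enrichment(fit, counts, nTotal)
    df$enrichment <- enr$enrichment[match(df$component, enr$class)]
  }
  df <- rbind(df, data.frame(component = "residual",
                             sigma2 = fit@sigma2e,
                             h2_f = 1 - sum(prop),
                             se_sigma2 = unname(fit@se["residual"]),
                             se_h2 = NA,
                             enrichment = if (!is.null(counts)) NA else NULL))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published reporting tables for milk production traits
#'
#' Reference tables from a large multi-omics study of Holstein bulls
#' (23,566 animals, ~3.0 million imputed sequence variants), shipped as
#' plain text under \code{inst/extdata} and used by the worked examples
#' of the reporting arithmetic:
#' \describe{
#'   \item{milkReliabilityPanels()}{GBLUP validation reliability (\%)
#'     for five milk production traits under the routine 671K genotype
#'     panel and the functionally enriched 625K panel.}
#'   \item{milkReliabilityModels()}{Validation reliability (\%) for the
#'     same traits under GBLUP, MultiBLUP, BayesR and BayesRC.}
#'   \item{milkClassProportions()}{Per-class variance proportions from
#'     the ten-GRM joint partition (nine mammary functional classes
#'     plus the non-functional rest), with per-class variant counts.}
#' }
#'
#' @return a data.frame (first column = row label).
#' @name milkTables
NULL

milkTable <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "lactovar"),
                    check.names = FALSE)
}

#' @rdname milkTables
#' @export
milkReliabilityPanels <- function() milkTable("milk_reliability_panels.tsv")

#' @rdname milkTables
#' @export
milkReliabilityModels <- function() milkTable("milk_reliability_models.tsv")

#' @rdname milkTables
#' @export
milkClassProportions <- function() milkTable("milk_class_proportions.tsv")
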