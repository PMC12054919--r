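#' Hyper-editing transform: collapse A to G
#'
#' Replaces every A with G, the reduced-alphabet trick that lets heavily
#' A-to-I edited reads (read as G) align to the reference despite their
#' many A/G mismatches.  Idempotent; apply to both reads and reference.
#'
#' @param seq character vector of DNA sequences over \{A, C, G, T, N\}.
#' @return the transformed sequences.
#' @examples
#' hyperEditTransform("AACGT")  # "GGCGT"
#' @export
hyperEditTransform <- function(seq) {
  stopifnot2(all(grepl("^[ACGTN]*$", seq)), "non-DNA characters in sequence")
  chartr("A", "G", seq)
}

#' Realign transformed reads to the transformed reference
#'
#' Exact-seed plus Hamming-extension matcher for ungapped reads: each
#' A-collapsed read is placed at every position where its first
#' \code{seedLength} bases match the A-collapsed reference exactly, the
#' full-length Hamming distance is computed there, and the best
#' placement with at most \code{maxMismatch} mismatches is kept (ties
#' broken leftmost).  Reads with no acceptable placement are discarded.
#'
#' @param reads data.frame with columns \code{read_id}, \code{seq} (and
#'   optionally \code{qual}).
#' @param reference named character vector of length 1: the original
#'   (untransformed) reference sequence.
#' @param maxMismatch maximum Hamming mismatches on the transformed
#'   alphabet (default 2).
#' @param seedLength exact-match seed at the read 5' end (default 20).
#' @return data.frame: read_id, pos (1-based placement on the
#'   reference), mismatches (transformed-alphabet count).
#' @export
realignTransformed <- function(reads, reference, maxMismatch = 2,
                               seedLength = 20) {
  refT <- Biostrings::DNAString(hyperEditTransform(unname(reference)[1]))
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rdT <- hyperEditTransform(reads$seq[i])
    L <- nchar(rdT)
    sl <- min(seedLength, L)
    hits <- Biostrings::matchPattern(substr(rdT, 1, sl), refT)
    st <- Biostrings::start(hits)
    st <- st[st + L - 1 <= length(refT)]
    if (!length(st)) next
    best <- NULL
    for (s in st) {
      mm <- sum(strsplit(rdT, "")[[1]] !=
                strsplit(as.character(Biostrings::subseq(refT, s, s + L - 1)),
                         "")[[1]])
      if (mm <= maxMismatch && (is.null(best) || mm < best$mm)) {
        best <- list(pos = s, mm = mm)
        if (mm == 0) break
      }
    }
    if (!is.null(best))
      out[[i]] <- data.frame(read_id = reads$read_id[i], pos = best$pos,
                             mismatches = best$mm, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    data.frame(read_id = character(), pos = integer(),
               mismatches = integer(), stringsAsFactors = FALSE)
  else res
}

#' Classify a candidate hyper-edited read
#'
#' Given a read placed on the original (untransformed) reference, decide
#' whether it qualifies as an edited read.  The rules: the A-to-G
#' mismatch count must reach 5\% of the read length (at least three
#' mismatches for reads of 60 bp or shorter); A-to-G mismatches must
#' exceed 80\% of all mismatches; mean Phred quality > 25; ambiguous
#' (N) fraction <= 10\%; no mono-/di-nucleotide motif repeated more
#' than \code{maxSimpleRepeat} times; no homopolymer longer than
#' \code{maxHomopolymer}.  T-to-C mismatches are counted as A-to-G on
#' the opposite strand (unstranded library).
#'
#' @param readSeq read sequence (character scalar).
#' @param refWindow reference sequence under the read (same length).
#' @param qual Phred+33 quality string (same length); \code{NULL} skips
#'   the quality rule.
#' @param maxSimpleRepeat,maxHomopolymer repeat-filter limits (defaults
#'   10 and 20).
#' @return list: pass (logical), nAG, nMismatch, meanPhred, agPositions
#'   (1-based offsets of A->G mismatches within the read, T->C reported
#'   on its own in tcPositions).
#' @export
classifyCandidateRead <- function(readSeq, refWindow, qual = NULL,
                                  maxSimpleRepeat = 10, maxHomopolymer = 20) {
  stopifnot2(nchar(readSeq) == nchar(refWindow),
             "read/reference window length mismatch")
  rd <- strsplit(readSeq, "")[[1]]
  rf <- strsplit(refWindow, "")[[1]]
  L <- length(rd)

  mm <- which(rd != rf & rd != "N" & rf != "N")
  ag <- mm[rf[mm] == "A" & rd[mm] == "G"]
  tc <- mm[rf[mm] == "T" & rd[mm] == "C"]
  nEdit <- length(ag) + length(tc)           # collapsed A->G channel
  nMM <- length(mm)

  need <- if (L <= 60) 3 else ceiling(0.05 * L)
  meanPhred <- if (is.null(qual)) Inf else
    mean(as.integer(charToRaw(qual)) - 33L)
  nFrac <- mean(rd == "N")

  pass <- nEdit >= need &&
    nMM > 0 && nEdit / nMM > 0.8 &&
    meanPhred > 25 &&
    nFrac <= 0.10 &&
    !hasSimpleRepeat(readSeq, maxSimpleRepeat) &&
    !hasHomopolymer(readSeq, maxHomopolymer)

  list(pass = pass, nAG = length(ag), nTC = length(tc), nMismatch = nMM,
       meanPhred = meanPhred, agPositions = ag, tcPositions = tc)
}

# mono- or di-nucleotide motif repeated more than maxRep times in a row
hasSimpleRepeat <- function(seq, maxRep) {
  for (k in 1:2) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, maxRep)
    if (grepl(pat, seq)) return(TRUE)
  }
  FALSE
}

hasHomopolymer <- function(seq, maxRun) {
  grepl(sprintf("([ACGT])\\1{%d,}", maxRun), seq)
}

#' RNA editing level
#'
#' \deqn{level = (mappedG + unmappedG) / (mappedDepth + unmappedG)}
#' where \code{mappedG} and \code{mappedDepth} count G-carrying reads
#' and total depth at the site among normally mapped reads, and
#' \code{unmappedG} counts G-carrying reads recovered by the
#' hyper-editing realignment.  Zero when the denominator is zero.
#'
#' @param mappedG,unmappedG,mappedDepth nonnegative counts with
#'   \code{mappedG <= mappedDepth}.
#' @return the editing level in [0, 1].
#' @examples
#' editingLevel(3, 2, 8)  # 0.5
#' @export
editingLevel <- function(mappedG, unmappedG, mappedDepth) {
  stopifnot2(all(c(mappedG, unmappedG, mappedDepth) >= 0),
             "counts must be nonnegative")
  stopifnot2(all(mappedG <= mappedDepth), "mappedG exceeds mappedDepth")
  den <- mappedDepth + unmappedG
  ifelse(den == 0, 0, (mappedG + unmappedG) / den)
}

#' Collapse T-to-C sites onto the A-to-G channel
#'
#' The library is unstranded, so A-to-I editing on the opposite strand
#' appears as T-to-C; since genuine T-to-C editing is rare in bovines,
#' all T-to-C sites are relabelled A-to-G, and counts are merged when a
#' locus carries both labels.
#'
#' @param sites data.frame with columns chrom, pos, type ("A-to-G" or
#'   "T-to-C"), mapped_G, unmapped_G, mapped_depth (and optionally
#'   sample).
#' @return the collapsed site table, one row per (sample,) locus.
#' @export
collapseStrand <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  sites$type[sites$type == "T-to-C"] <- "A-to-G"
  keys <- c(intersect("sample", names(sites)), "chrom", "pos", "type")
  agg <- stats::aggregate(sites[c("mapped_G", "unmapped_G", "mapped_depth")],
                          by = sites[keys], FUN = sum)
  agg <- agg[do.call(order, agg[keys]), ]
  rownames(agg) <- NULL
  agg
}

#' Single-linkage editing-cluster calling
#'
#' Chains consecutive same-chromosome sites whose gap is at most
#' \code{maxGap} bp into clusters; a cluster runs from its first to its
#' last member site (1-based inclusive length).  Singleton sites form
#' singleton clusters.
#'
#' @param sites data.frame with columns chrom, pos (1-based); sorted
#'   internally (with a warning) if needed.
#' @param maxGap maximum gap between consecutive member sites (default
#'   100).
#' @return list: \code{clusters} (data.frame: chrom, start, end, length,
#'   n_sites), \code{summary} (data.frame: mean_length,
#'   mean_sites_per_cluster, n_clusters).
#' @export
callClusters <- function(sites, maxGap = 100) {
  if (nrow(sites) == 0)
    return(list(clusters = data.frame(), summary = data.frame(
      mean_length = NA_real_, mean_sites_per_cluster = NA_real_,
      n_clusters = 0L)))
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    warning("sites were not sorted; sorting internally")
    sites <- sites[o, ]
  }
  newClust <- c(TRUE, sites$chrom[-1] != sites$chrom[-nrow(sites)] |
                  diff(sites$pos) > maxGap)
  id <- cumsum(newClust)
  cl <- data.frame(
    chrom = tapply(sites$chrom, id, `[`, 1),
    start = as.vector(tapply(sites$pos, id, min)),
    end = as.vector(tapply(sites$pos, id, max)))
  cl$length <- cl$end - cl$start + 1
  cl$n_sites <- as.vector(table(id))
  rownames(cl) <- NULL
  list(clusters = cl,
       summary = data.frame(mean_length = mean(cl$length),
                            mean_sites_per_cluster = mean(cl$n_sites),
                            n_clusters = nrow(cl)))
}

#' Detect RNA editing sites from a read fixture
#'
#' Full desk-scale pipeline: reads whose stated placement shows more
#' than \code{mismatchThreshold} mismatches against the reference are
#' treated as unmapped and sent through the hyper-editing branch
#' (A-collapse, realignment, candidate-read classification); passing
#' reads vote for A->G (or T->C, collapsed) sites.  Editing levels then
#' combine the mapped-read G counts and depth with the recovered
#' unmapped-read G counts.  Sites are kept when supported by at least
#' one passing edited read and \code{minSupport} total G-carrying
#' reads.
#'
#' @param reads data.frame: read_id, chrom, pos (1-based), seq, qual.
#' @param reference named character vector of length 1.
#' @param mismatchThreshold mapped/unmapped split (default 3: reads with
#'   > 3 mismatches go to the hyper-editing branch).
#' @param maxGap cluster gap (default 100).
#' @param minSupport minimum total edited-read support per site
#'   (default 2).
#' @param ... passed to \code{\link{classifyCandidateRead}}.
#' @return list: \code{sites} (data.frame: chrom, pos, type, mapped_G,
#'   unmapped_G, mapped_depth, level), \code{clusters} (from
#'   \code{\link{callClusters}}).
#' @export
detectEditingSites <- function(reads, reference, mismatchThreshold = 3,
                               maxGap = 100, minSupport = 2, ...) {
  refChars <- strsplit(unname(reference)[1], "")[[1]]
  L <- length(refChars)
  rl <- nchar(reads$seq)

  # split mapped vs unmapped by mismatch count at the stated placement
  nmm <- integer(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rd <- strsplit(reads$seq[i], "")[[1]]
    win <- refChars[reads$pos[i]:(reads$pos[i] + rl[i] - 1L)]
    nmm[i] <- sum(rd != win)
  }
  mapped <- reads[nmm <= mismatchThreshold, , drop = FALSE]
  unmapped <- reads[nmm > mismatchThreshold, , drop = FALSE]

  # hyper-editing branch
  votes <- list()
  if (nrow(unmapped)) {
    aln <- realignTransformed(unmapped, reference, maxMismatch = 2, ...)
    for (i in seq_len(nrow(aln))) {
      rr <- unmapped[match(aln$read_id[i], unmapped$read_id), ]
      rl1 <- nchar(rr$seq)
      win <- paste(refChars[aln$pos[i]:(aln$pos[i] + rl1 - 1L)],
                   collapse = "")
      cls <- classifyCandidateRead(rr$seq, win, rr$qual)
      if (cls$pass) {
        if (length(cls$agPositions))
          votes[[length(votes) + 1L]] <- data.frame(
            pos = aln$pos[i] + cls$agPositions - 1L, type = "A-to-G",
            read_id = rr$read_id, stringsAsFactors = FALSE)
        if (length(cls$tcPositions))
          votes[[length(votes) + 1L]] <- data.frame(
            pos = aln$pos[i] + cls$tcPositions - 1L, type = "T-to-C",
            read_id = rr$read_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(votes))
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   type = character(), mapped_G = integer(),
                                   unmapped_G = integer(),
                                   mapped_depth = integer(),
                                   level = numeric(),
                                   stringsAsFactors = FALSE),
                clusters = callClusters(data.frame(chrom = character(),
                                                   pos = integer()))))
  vt <- do.call(rbind, votes)
  chromName <- names(reference)[1]
  if (is.null(chromName)) chromName <- unique(reads$chrom)[1]

  counts <- stats::aggregate(read_id ~ pos + type, vt, length)
  names(counts)[3] <- "unmapped_G"

  # mapped-channel depth and G counts at candidate positions
  posList <- sort(unique(counts$pos))
  mappedG <- mappedDepth <- stats::setNames(integer(length(posList)),
                                            posList)
  for (i in seq_len(nrow(mapped))) {
    s <- mapped$pos[i]; e <- s + nchar(mapped$seq[i]) - 1L
    ov <- posList[posList >= s & posList <= e]
    if (!length(ov)) next
    rd <- strsplit(mapped$seq[i], "")[[1]]
    for (pp in ov) {
      key <- as.character(pp)
      mappedDepth[key] <- mappedDepth[key] + 1L
      base <- rd[pp - s + 1L]
      isEdited <- (refChars[pp] == "A" && base == "G") ||
        (refChars[pp] == "T" && base == "C")
      if (isEdited) mappedG[key] <- mappedG[key] + 1L
    }
  }

  sites <- data.frame(chrom = chromName, pos = counts$pos,
                      type = counts$type,
                      mapped_G = unname(mappedG[as.character(counts$pos)]),
                      unmapped_G = counts$unmapped_G,
                      mapped_depth = unname(mappedDepth[as.character(counts$pos)]),
                      stringsAsFactors = FALSE)
  sites$sample <- NULL
  sites <- collapseStrand(sites)
  sites <- sites[sites$mapped_G + sites$unmapped_G >= minSupport, ,
                 drop = FALSE]
  sites$level <- editingLevel(sites$mapped_G, sites$unmapped_G,
                              sites$mapped_depth)
  rownames(sites) <- NULL
  list(sites = sites, clusters = callClusters(sites[c("chrom", "pos")],
                                              maxGap = maxGap))
}

#' Compare editing between two stages
#'
#' A site is stage-qualified when present in every sample of that
#' stage; specific = qualified in exactly one stage, common = qualified
#' in both.  Differential sites are common sites whose per-sample
#' editing levels differ between stages by a Wilcoxon rank-sum test
#' with Benjamini-Hochberg adjusted p < 0.05.
#'
#' @param siteTables named list (sample -> site data.frame with chrom,
#'   pos, level).
#' @param groupLabels named character/factor: sample -> stage (exactly 2
#'   stages, each with >= 2 samples).
#' @return list: specific (data.frame chrom, pos, stage), common
#'   (data.frame chrom, pos), differential (data.frame chrom, pos, p,
#'   p_adj).
#' @export
compareStages <- function(siteTables, groupLabels) {
  stopifnot2(all(names(siteTables) %in% names(groupLabels)),
             "groupLabels must cover every sample")
  groups <- split(names(siteTables), unname(groupLabels[names(siteTables)]))
  stopifnot2(length(groups) == 2, "need exactly two stages")
  stopifnot2(all(lengths(groups) >= 2), "each stage needs >= 2 samples")

  keyOf <- function(df) paste(df$chrom, df$pos, sep = ":")
  present <- lapply(siteTables, keyOf)
  qual <- lapply(groups, function(ss) Reduce(intersect, present[ss]))

  commonKeys <- intersect(qual[[1]], qual[[2]])
  spec1 <- setdiff(qual[[1]], qual[[2]])
  spec2 <- setdiff(qual[[2]], qual[[1]])
  splitKey <- function(keys, extra = NULL) {
    if (!length(keys))
      return(data.frame(chrom = character(), pos = integer()))
    parts <- strsplit(keys, ":")
    df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                     pos = as.integer(vapply(parts, `[`, "", 2)),
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df$stage <- extra
    df
  }
  specific <- rbind(splitKey(spec1, names(groups)[1]),
                    splitKey(spec2, names(groups)[2]))

  differential <- data.frame(chrom = character(), pos = integer(),
                             p = numeric(), p_adj = numeric())
  if (length(commonKeys)) {
    levelAt <- function(sample, keys) {
      df <- siteTables[[sample]]
      df$level[match(keys, keyOf(df))]
    }
    p <- vapply(commonKeys, function(kk) {
      l1 <- vapply(groups[[1]], function(s) levelAt(s, kk), 0)
      l2 <- vapply(groups[[2]], function(s) levelAt(s, kk), 0)
      pv <- suppressWarnings(stats::wilcox.test(l1, l2)$p.value)
      if (!is.finite(pv)) 1 else pv       # fully tied levels: no signal
    }, 0)
    padj <- stats::p.adjust(p, method = "BH")
    differential <- cbind(splitKey(commonKeys), p = unname(p),
                          p_adj = unname(padj))
    differential <- differential[differential$p_adj < 0.05, , drop = FALSE]
    rownames(differential) <- NULL
  }
  list(specific = specific, common = splitKey(commonKeys),
       differential = differential)
}
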