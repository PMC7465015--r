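# Retrocopy detection from discordant read pairs over the parental gene.
#
# Two evidence classes drive the caller: exon-to-exon pairs whose genomic
# separation is inflated by the introns missing from the retrocopy
# template (JUNCTION_SPANNING), and pairs with one mate on the parental
# gene and the other at the insertion locus (TRANS_MATE). A locus is
# called CONFIDENT only when both classes support it.

SIGNAL_CLASSES <- c("CONCORDANT", "JUNCTION_SPANNING", "TRANS_MATE", "OTHER")

#' Classify read pairs over the parental gene locus
#'
#' Assigns every pair exactly one signal class:
#' * `JUNCTION_SPANNING` -- both mates map within gene exons, in different
#'   exons, with a template span exceeding `insertMean + k * insertSd`
#'   (intron-scale inflation implying an intronless template);
#' * `TRANS_MATE` -- exactly one mate maps within the gene span and the
#'   other maps elsewhere, beyond `transRadius` of the gene (or on another
#'   chromosome);
#' * `CONCORDANT` -- proper forward/reverse geometry with a template span
#'   within `k` SD of the library insert size;
#' * `OTHER` -- everything else, including pairs with unmapped mates
#'   (never an error).
#'
#' @param pairs pair table from [readPairs()].
#' @param gene the parental [GeneModel].
#' @param insertMean,insertSd library insert-size statistics, bp.
#' @param k discordance threshold in SD units (default 4: separates
#'   intron-scale span inflation from library-size noise).
#' @param transRadius exclusion radius around the gene within which a
#'   non-gene mate is treated as local noise rather than trans evidence.
#' @return `pairs` with added columns `class`, `exon1`, `exon2`,
#'   `templateSpan`.
#' @export
classifyPairs <- function(pairs, gene, insertMean = 400, insertSd = 50,
                          k = 4, transRadius = 10000) {
  n <- nrow(pairs)
  gr <- geneRange(gene)
  gChrom <- geneChrom(gene)
  gStart <- GenomicRanges::start(gr); gEnd <- GenomicRanges::end(gr)
  exS <- IRanges::start(exons(gene)); exE <- IRanges::end(exons(gene))

  midExon <- function(chrom, pos, end) {
    mid <- as.integer((pos + end) %/% 2L)
    out <- rep(NA_integer_, length(pos))
    onGene <- !is.na(chrom) & chrom == gChrom
    for (kk in seq_along(exS)) {
      hit <- onGene & mid >= exS[kk] & mid <= exE[kk]
      out[hit] <- kk
    }
    out
  }
  exon1 <- midExon(pairs$chrom1, pairs$pos1, pairs$end1)
  exon2 <- midExon(pairs$chrom2, pairs$pos2, pairs$end2)

  mapped1 <- !is.na(pairs$chrom1); mapped2 <- !is.na(pairs$chrom2)
  sameChrom <- mapped1 & mapped2 & pairs$chrom1 == pairs$chrom2
  span <- rep(NA_integer_, n)
  span[sameChrom] <- pmax(pairs$end1[sameChrom], pairs$end2[sameChrom]) -
    pmin(pairs$pos1[sameChrom], pairs$pos2[sameChrom]) + 1L

  inGene <- function(chrom, pos, end) {
    !is.na(chrom) & chrom == gChrom & end >= gStart & pos <= gEnd
  }
  g1 <- inGene(pairs$chrom1, pairs$pos1, pairs$end1)
  g2 <- inGene(pairs$chrom2, pairs$pos2, pairs$end2)
  nearGene <- function(chrom, pos, end) {
    !is.na(chrom) & chrom == gChrom &
      end >= gStart - transRadius & pos <= gEnd + transRadius
  }
  far1 <- mapped1 & (!is.na(pairs$chrom1) & pairs$chrom1 != gChrom |
                       !nearGene(pairs$chrom1, pairs$pos1, pairs$end1))
  far2 <- mapped2 & (!is.na(pairs$chrom2) & pairs$chrom2 != gChrom |
                       !nearGene(pairs$chrom2, pairs$pos2, pairs$end2))

  cutoff <- insertMean + k * insertSd
  junction <- !is.na(exon1) & !is.na(exon2) & exon1 != exon2 &
    !is.na(span) & span > cutoff
  trans <- (g1 & far2) | (g2 & far1)

  # proper geometry: same chromosome, forward/reverse with the forward mate
  # leftmost, span within k SD of the insert size
  fr <- sameChrom & !is.na(pairs$strand1) & !is.na(pairs$strand2) &
    pairs$strand1 != pairs$strand2
  leftFwd <- rep(FALSE, n)
  leftFwd[fr] <- ifelse(pairs$pos1[fr] <= pairs$pos2[fr],
                        pairs$strand1[fr] == "+", pairs$strand2[fr] == "+")
  concord <- fr & leftFwd & !is.na(span) & span <= cutoff & span >= 1L

  cls <- rep("OTHER", n)
  cls[concord] <- "CONCORDANT"
  cls[trans] <- "TRANS_MATE"
  cls[junction] <- "JUNCTION_SPANNING"
  pairs$class <- cls
  pairs$exon1 <- exon1
  pairs$exon2 <- exon2
  pairs$templateSpan <- span
  pairs
}

#' Cluster the outside mates of trans pairs
#'
#' Single-linkage clustering of the non-gene ("outside") mate positions of
#' `TRANS_MATE` pairs: two mates join a cluster iff they are on the same
#' chromosome and the gap between them is at most `clusterWindow`.
#' Clusters are reported sorted by (chrom, start).
#'
#' @param pairs classified pair table ([classifyPairs()]); rows with class
#'   other than `TRANS_MATE` are ignored.
#' @param gene the parental [GeneModel].
#' @param clusterWindow linkage gap, bp (default `insertMean + 4*insertSd`
#'   when computed by the caller; 600 here).
#' @return a `data.frame` with one row per cluster: `chrom`, `start`,
#'   `end`, `n` (mate count), `nPlus`, `nMinus` (outside-mate strand
#'   counts), `plusEnd` (rightmost end of a forward outside mate),
#'   `minusStart` (leftmost start of a reverse outside mate).
#' @export
clusterTransMates <- function(pairs, gene, clusterWindow = 600) {
  tm <- pairs[pairs$class == "TRANS_MATE", , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n = integer(), nPlus = integer(),
                      nMinus = integer(), plusEnd = integer(),
                      minusStart = integer(), stringsAsFactors = FALSE)
  if (nrow(tm) == 0L) return(empty)
  gr <- geneRange(gene)
  gChrom <- geneChrom(gene)
  gStart <- GenomicRanges::start(gr); gEnd <- GenomicRanges::end(gr)
  inGene1 <- !is.na(tm$chrom1) & tm$chrom1 == gChrom &
    tm$end1 >= gStart & tm$pos1 <= gEnd
  pick <- function(f1, f2) ifelse(inGene1, f2, f1)
  out <- data.frame(
    chrom = pick(tm$chrom1, tm$chrom2),
    pos = pick(tm$pos1, tm$pos2),
    end = pick(tm$end1, tm$end2),
    strand = pick(tm$strand1, tm$strand2),
    stringsAsFactors = FALSE)
  out <- out[!is.na(out$chrom), , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  newClust <- c(TRUE, out$chrom[-1L] != out$chrom[-nrow(out)] |
                  out$pos[-1L] - out$end[-nrow(out)] > clusterWindow)
  cid <- cumsum(newClust)
  res <- do.call(rbind, lapply(split(seq_len(nrow(out)), cid), function(ii) {
    o <- out[ii, , drop = FALSE]
    plus <- o$strand == "+"
    data.frame(chrom = o$chrom[1L], start = min(o$pos), end = max(o$end),
               n = nrow(o), nPlus = sum(plus), nMinus = sum(!plus),
               plusEnd = if (any(plus)) max(o$end[plus]) else NA_integer_,
               minusStart = if (any(!plus)) min(o$pos[!plus]) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Split-read support for the exon-junction signal
#'
#' Counts reads soft-clipped at an exon boundary whose clipped bases match
#' the adjacent exon: a read ending exactly at the 3' end of exon k with a
#' right clip of at least `minClip` bases equal to the start of exon k+1
#' (and the mirror case) came from an intronless template. Supplements the
#' pair-geometry junction evidence.
#'
#' @param pairs classified pair table (needs `cigar*`, `seq*`, clip columns).
#' @param gene the parental [GeneModel].
#' @param minClip minimum clip length considered alignable (default 12 bp:
#'   shorter clips match adjacent sequence too easily by chance).
#' @return integer count of supporting reads.
#' @export
splitReadSupport <- function(pairs, gene, minClip = 12L) {
  exS <- IRanges::start(exons(gene)); exE <- IRanges::end(exons(gene))
  w <- IRanges::width(exons(gene))
  cum <- cumsum(w)
  mrna <- as.character(mrnaSeq(gene))
  if (geneStrand(gene) == "-") mrna <- revcompChar(mrna)  # genomic forward
  # genomic-forward exon sequences
  exSeq <- substring(mrna, c(1L, cum[-length(cum)] + 1L), cum)
  gChrom <- geneChrom(gene)
  count <- 0L
  for (m in 1:2) {
    chrom <- pairs[[paste0("chrom", m)]]
    pos <- pairs[[paste0("pos", m)]]
    endp <- pairs[[paste0("end", m)]]
    sq <- pairs[[paste0("seq", m)]]
    cl <- pairs[[paste0("clipLeft", m)]]
    cr <- pairs[[paste0("clipRight", m)]]
    onGene <- !is.na(chrom) & chrom == gChrom
    # right clip at an exon 3' end, matching the next exon's start
    for (kk in seq_along(exS)) {
      if (kk < length(exS)) {
        cand <- which(onGene & endp == exE[kk] & cr >= minClip)
        for (j in cand) {
          clip <- substr(sq[j], nchar(sq[j]) - cr[j] + 1L, nchar(sq[j]))
          need <- min(nchar(clip), 20L)
          if (substr(clip, 1L, need) ==
              substr(exSeq[kk + 1L], 1L, need)) count <- count + 1L
        }
      }
      if (kk > 1L) {
        cand <- which(onGene & pos == exS[kk] & cl >= minClip)
        for (j in cand) {
          clip <- substr(sq[j], 1L, cl[j])
          need <- min(nchar(clip), 20L)
          prevSeq <- exSeq[kk - 1L]
          if (substr(clip, nchar(clip) - need + 1L, nchar(clip)) ==
              substr(prevSeq, nchar(prevSeq) - need + 1L, nchar(prevSeq)))
            count <- count + 1L
        }
      }
    }
  }
  count
}

#' Call retrocopy insertions from both evidence classes
#'
#' Every trans-mate cluster with at least `minTransCandidate` mates becomes
#' a call; a call is `CONFIDENT` only when the cluster has at least
#' `minTrans` mates *and* genome-wide junction support (exon-to-exon pairs
#' plus qualifying split reads) reaches `minJunction` -- the
#' both-signals rule. Calls overlapping an annotated reference retrocopy
#' fragment are demoted to `FRAGMENT`. The reported interval is the
#' innermost breakpoint interval bracketed by the forward/reverse outside
#' mates (its overlap is the target-site-duplication footprint); the full
#' cluster extent is kept in `clusterStart`/`clusterEnd`.
#'
#' Orientation is the strand consensus of the outside mates (>= 80%
#' agreement required, ties and weaker mixes give `"unknown"`).
#'
#' @param pairs classified pair table.
#' @param gene the parental [GeneModel].
#' @param minJunction,minTrans support required for `CONFIDENT` (default
#'   3/3; loci meeting only the 2/2 floor remain `CANDIDATE`, so a
#'   two-read locus is reported but flagged for follow-up, not called).
#' @param minTransCandidate cluster floor for reporting at all.
#' @param clusterWindow linkage gap for [clusterTransMates()].
#' @param minClip split-read clip threshold ([splitReadSupport()]).
#' @param fragments optional `GRanges` of annotated reference retrocopy
#'   fragments.
#' @return a [GenomicRanges::GRanges] of calls with metadata columns
#'   `nJunctionPairs`, `nSplitReads`, `nTransPairs`, `orientation`,
#'   `status`, `clusterStart`, `clusterEnd`. Zero calls is a valid result.
#' @export
callInsertions <- function(pairs, gene, minJunction = 3L, minTrans = 3L,
                           minTransCandidate = 2L, clusterWindow = 600,
                           minClip = 12L, fragments = NULL) {
  nJunction <- sum(pairs$class == "JUNCTION_SPANNING")
  nSplit <- splitReadSupport(pairs, gene, minClip = minClip)
  clusters <- clusterTransMates(pairs, gene, clusterWindow = clusterWindow)
  clusters <- clusters[clusters$n >= minTransCandidate, , drop = FALSE]
  if (nrow(clusters) == 0L) {
    gr0 <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr0) <- S4Vectors::DataFrame(
      nJunctionPairs = integer(), nSplitReads = integer(),
      nTransPairs = integer(), orientation = character(),
      status = character(), clusterStart = integer(),
      clusterEnd = integer())
    return(gr0)
  }
  # innermost breakpoint interval from the facing outside mates
  bkStart <- ifelse(is.na(clusters$minusStart), clusters$start,
                    pmin(clusters$minusStart,
                         ifelse(is.na(clusters$plusEnd), clusters$minusStart,
                                clusters$plusEnd)))
  bkEnd <- ifelse(is.na(clusters$plusEnd), clusters$end,
                  pmax(clusters$plusEnd,
                       ifelse(is.na(clusters$minusStart), clusters$plusEnd,
                              clusters$minusStart)))
  orient <- rep("unknown", nrow(clusters))
  fracPlus <- clusters$nPlus / clusters$n
  orient[fracPlus >= 0.8] <- "+"
  orient[fracPlus <= 0.2] <- "-"
  status <- ifelse(clusters$n >= minTrans &
                     (nJunction + nSplit) >= minJunction,
                   "CONFIDENT", "CANDIDATE")
  calls <- GenomicRanges::GRanges(clusters$chrom,
    IRanges::IRanges(bkStart, bkEnd),
    nJunctionPairs = nJunction, nSplitReads = nSplit,
    nTransPairs = clusters$n, orientation = orient, status = status,
    clusterStart = clusters$start, clusterEnd = clusters$end)
  if (!is.null(fragments) && length(fragments)) {
    hit <- GenomicRanges::countOverlaps(calls, fragments,
                                        ignore.strand = TRUE) > 0L
    calls$status[hit] <- "FRAGMENT"
  }
  calls
}

#' Scan one sample's alignments for retrocopy insertions
#'
#' Convenience wrapper: read pairs, classify, call; logs per-class pair
#' counts.
#'
#' @param samPath SAM file path.
#' @param gene the parental [GeneModel].
#' @param insertMean,insertSd,k,transRadius see [classifyPairs()].
#' @param clusterWindow linkage gap; default `insertMean + 4 * insertSd`.
#' @param ... passed to [callInsertions()].
#' @param verbose emit per-class counters via `message()`.
#' @return list with `pairs` (classified table) and `calls` (`GRanges`).
#' @export
scanSample <- function(samPath, gene, insertMean = 400, insertSd = 50,
                       k = 4, transRadius = 10000,
                       clusterWindow = insertMean + 4 * insertSd,
                       ..., verbose = FALSE) {
  pairs <- readPairs(samPath)
  pairs <- classifyPairs(pairs, gene, insertMean = insertMean,
                         insertSd = insertSd, k = k,
                         transRadius = transRadius)
  if (verbose) {
    tab <- table(factor(pairs$class, levels = SIGNAL_CLASSES))
    message(sprintf("[scan] %s: %s", basename(samPath),
                    paste(names(tab), tab, sep = "=", collapse = " ")))
  }
  calls <- callInsertions(pairs, gene, clusterWindow = clusterWindow, ...)
  list(pairs = pairs, calls = calls)
}

#' Screen a cohort of SAM files
#'
#' Runs [scanSample()] over each file; unreadable files are logged and
#' marked `failed` without aborting the batch. Samples with zero calls are
#' still listed (one row, `NA` call fields).
#'
#' @param samPaths named character vector of SAM paths (names become
#'   sample identifiers; basenames used otherwise).
#' @param gene the parental [GeneModel].
#' @param ... passed to [scanSample()].
#' @return a `data.frame`: one row per sample x call, with `sample`,
#'   `status` (`ok`/`failed`), call coordinates and support columns.
#' @export
screenCohort <- function(samPaths, gene, ...) {
  ids <- names(samPaths) %||% basename(samPaths)
  if (is.null(names(samPaths))) names(samPaths) <- ids
  rows <- lapply(ids, function(id) {
    res <- tryCatch(scanSample(samPaths[[id]], gene, ...),
                    error = function(e) {
                      message("[screenCohort] sample ", id, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res))
      return(data.frame(sample = id, status = "failed",
                        chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, callStatus = NA_character_,
                        nJunctionPairs = NA_integer_,
                        nTransPairs = NA_integer_,
                        orientation = NA_character_,
                        stringsAsFactors = FALSE))
    calls <- res$calls
    if (length(calls) == 0L)
      return(data.frame(sample = id, status = "ok",
                        chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, callStatus = NA_character_,
                        nJunctionPairs = NA_integer_,
                        nTransPairs = NA_integer_,
                        orientation = NA_character_,
                        stringsAsFactors = FALSE))
    data.frame(sample = id, status = "ok",
               chrom = as.character(GenomicRanges::seqnames(calls)),
               start = GenomicRanges::start(calls),
               end = GenomicRanges::end(calls),
               callStatus = calls$status,
               nJunctionPairs = calls$nJunctionPairs,
               nTransPairs = calls$nTransPairs,
               orientation = calls$orientation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
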