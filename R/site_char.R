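# Insertion-site characterization: target site duplication detection,
# G/C content of the breakpoint window, L1 endonuclease motif scanning,
# conserved-element counting and UTR truncation calls.

#' Find the target site duplication at an insertion
#'
#' An L1-mediated insertion duplicates the bases at the integration site,
#' leaving the same short sequence immediately 5' of the insert and
#' immediately 3' of it. Given sequence context ending at the 5' junction
#' and context beginning at the 3' junction, the TSD is the longest string
#' that is simultaneously a suffix of the former and a prefix of the
#' latter.
#'
#' The anchored definition admits exactly one candidate per length, so the
#' search walks lengths from `maxLen` down and returns the first (longest)
#' candidate with at most `maxMismatch` mismatches; with
#' `maxMismatch = 0` that is the longest exact duplication.
#'
#' @param junction5Context sequence ending at the 5' junction
#'   (`...flank + TSD`).
#' @param junction3Context sequence beginning at the 3' junction
#'   (`TSD + flank...`).
#' @param maxMismatch mismatches tolerated inside the duplication.
#' @param minLen,maxLen length bounds, bp. Duplications under 6 bp are
#'   indistinguishable from chance and are never reported.
#' @return a list with `tsdSeq`, `tsdLen`, `mismatches`, or `NULL` when no
#'   duplication of at least `minLen` exists.
#' @examples
#' findTsd("ACCATGAAATAAGTCAGACAGAG", "AAGTCAGACAGAGAAAGACAAGT")
#' @export
findTsd <- function(junction5Context, junction3Context, maxMismatch = 0L,
                    minLen = 6L, maxLen = 30L) {
  c5 <- checkDna(junction5Context, "junction5Context")
  c3 <- checkDna(junction3Context, "junction3Context")
  if (nchar(c5) < minLen || nchar(c3) < minLen)
    stop("junction contexts must be at least minLen (", minLen, ") bp",
         call. = FALSE)
  top <- min(maxLen, nchar(c5), nchar(c3))
  for (L in seq(top, minLen)) {
    suf <- substr(c5, nchar(c5) - L + 1L, nchar(c5))
    pre <- substr(c3, 1L, L)
    mism <- sum(strsplit(suf, "")[[1]] != strsplit(pre, "")[[1]])
    if (mism <= maxMismatch)
      return(list(tsdSeq = pre, tsdLen = L, mismatches = mism))
  }
  NULL
}

#' G/C percentage of a breakpoint window
#'
#' `100 * (#G + #C) / length`, rounded half-up to one decimal -- the
#' convention used when insertion-site windows (10 bp flank + TSD + 10 bp
#' flank) are tabulated. Ambiguity codes are rejected rather than
#' fractionally weighted.
#'
#' @param windowSeq A/C/G/T string.
#' @return numeric scalar, one decimal.
#' @examples
#' gcWindow("ATGCGC")  # 66.7
#' @export
gcWindow <- function(windowSeq) {
  w <- checkDna(windowSeq, "windowSeq")
  n <- nchar(w)
  gc <- nchar(gsub("[AT]", "", w))
  roundHalfUp(100 * gc / n, 1L)
}

#' Scan a window for the L1 endonuclease consensus motif
#'
#' The L1 integration machinery loosely prefers `TTAAAA` at its nick site.
#' The default scan covers the reference forward strand of the window
#' (site windows are conventionally printed forward-strand regardless of
#' retrocopy orientation); set `bothStrands` to also report
#' reverse-complement occurrences.
#'
#' @param windowSeq A/C/G/T string.
#' @param motif motif to search (default `TTAAAA`).
#' @param bothStrands also scan the reverse complement.
#' @return integer vector of 1-based forward-strand start offsets, or when
#'   `bothStrands = TRUE` a list with `forward` and `reverse` offsets
#'   (reverse offsets are forward-strand positions of the revcomp hit).
#' @examples
#' scanMotif("TTAAAATTAAAA")  # 1 and 7
#' @export
scanMotif <- function(windowSeq, motif = "TTAAAA", bothStrands = FALSE) {
  w <- checkDna(windowSeq, "windowSeq")
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  hit <- function(m) {
    if (nchar(m) > nchar(w)) return(integer(0))
    BiocGenerics::start(Biostrings::matchPattern(Biostrings::DNAString(m),
                                                 Biostrings::DNAString(w)))
  }
  fwd <- as.integer(hit(motif))
  if (!bothStrands) return(fwd)
  list(forward = fwd, reverse = as.integer(hit(revcompChar(motif))))
}

#' Count conserved elements near an insertion site
#'
#' Number of conserved-element intervals (e.g. from a multi-species
#' alignment conservation track) overlapping, by at least one base, the
#' window `[midpoint - radius, midpoint + radius]` around the insertion
#' site.
#'
#' @param insertionInterval a length-1 `GRanges`, or a list/vector with
#'   `chrom`, `start`, `end` (1-based inclusive).
#' @param ecr conserved elements: a `GRanges` or a BED path.
#' @param radius window half-width, bp (default 2500).
#' @return integer count.
#' @export
countEcr <- function(insertionInterval, ecr, radius = 2500L) {
  if (is.character(ecr)) ecr <- readBedIntervals(ecr)
  if (!is(insertionInterval, "GRanges")) {
    ii <- as.list(insertionInterval)
    insertionInterval <- GenomicRanges::GRanges(as.character(ii$chrom),
      IRanges::IRanges(as.integer(ii$start), as.integer(ii$end)))
  }
  if (length(ecr) == 0L) return(0L)
  mid <- (GenomicRanges::start(insertionInterval) +
            GenomicRanges::end(insertionInterval)) %/% 2L
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(insertionInterval),
    IRanges::IRanges(pmax(1L, mid - as.integer(radius)),
                     mid + as.integer(radius)))
  as.integer(GenomicRanges::countOverlaps(win, ecr, ignore.strand = TRUE))
}

#' Classify UTR truncation of a retrocopy
#'
#' Aligns the retrocopy sequence (mRNA orientation, polyA optionally
#' stripped) against the full parental mRNA with free end gaps on the mRNA
#' side; the unaligned mRNA prefix and suffix are the 5' and 3'
#' truncations. The ORF is intact when it is fully covered, gap-free and
#' translates without a premature stop.
#'
#' @param retroSeq retrocopy sequence, mRNA strand.
#' @param gene the parental [GeneModel].
#' @param minIdentity percent identity below which the sequence is
#'   rejected as not being a retrocopy of this gene.
#' @param stripPolyA remove a trailing A-run (>= 5 bp) before aligning.
#' @return a [TruncationReport].
#' @export
classifyTruncation <- function(retroSeq, gene, minIdentity = 90,
                               stripPolyA = TRUE) {
  retro <- checkDna(retroSeq, "retroSeq")
  if (stripPolyA) retro <- sub("A{5,}$", "", retro)
  aln <- alignToMrna(retro, gene, minIdentity = minIdentity)
  mlen <- mrnaLength(gene)
  sRange <- aln$subjectRange
  trunc5 <- IRanges::start(sRange) - 1L
  trunc3 <- mlen - IRanges::end(sRange)
  orfIv <- orf(gene)
  os <- IRanges::start(orfIv); oe <- IRanges::end(orfIv)
  covered <- trunc5 < os && IRanges::end(sRange) >= oe
  orfIntact <- FALSE
  if (covered) {
    p <- aln$patternAligned; s <- aln$subjectAligned
    sPos <- cumsum(s != "-") + trunc5  # subject position at each column
    inOrf <- s != "-" & sPos >= os & sPos <= oe
    insCols <- s == "-" & sPos >= os & sPos < oe  # insertions inside ORF
    noIndel <- !any(p[inOrf] == "-") && !any(insCols)
    if (noIndel) {
      orfRetro <- paste(p[inOrf], collapse = "")
      if (nchar(orfRetro) %% 3L == 0L) {
        aaOf <- function(x) as.character(Biostrings::translate(
          Biostrings::DNAString(x)))
        aa <- aaOf(orfRetro)
        aaParent <- aaOf(as.character(Biostrings::subseq(mrnaSeq(gene),
                                                         os, oe)))
        stopsAt <- function(a) {
          v <- gregexpr("*", a, fixed = TRUE)[[1]]
          v[v > 0L & v < nchar(a)]
        }
        # a premature stop disrupts the ORF only if the parent lacks a
        # stop at that codon (a difference introduced it)
        prem <- length(setdiff(stopsAt(aa), stopsAt(aaParent))) > 0L
        orfIntact <- !prem
      }
    }
  }
  new("TruncationReport", trunc5 = trunc5, trunc3 = trunc3,
      orfIntact = orfIntact, identity = aln$identity)
}

#' Characterize an insertion site end to end
#'
#' Combines TSD detection, the breakpoint G/C window, the motif scan, and
#' (when annotation is supplied) conserved-element and repeat context into
#' one [SiteReport]. All sequence is reported on the reference forward
#' strand; `strand` records the retrocopy orientation.
#'
#' @param name site label.
#' @param junction5Context,junction3Context see [findTsd()].
#' @param strand retrocopy orientation, `"+"` or `"-"`.
#' @param flankLen flank length included in the G/C window (default 10 bp).
#' @param insertionInterval optional site interval for annotation queries.
#' @param ecr optional conserved elements (`GRanges` or BED path).
#' @param repeats optional repeat annotation `GRanges` with a `name`
#'   metadata column containing `LINE`, `LTR` or `SINE`.
#' @param motif,radius,... passed to [scanMotif()], [countEcr()] and
#'   [findTsd()].
#' @return a [SiteReport].
#' @export
characterizeSite <- function(name, junction5Context, junction3Context,
                             strand = "+", flankLen = 10L,
                             insertionInterval = NULL, ecr = NULL,
                             repeats = NULL, motif = "TTAAAA",
                             radius = 2500L, ...) {
  c5 <- checkDna(junction5Context, "junction5Context")
  c3 <- checkDna(junction3Context, "junction3Context")
  tsd <- findTsd(c5, c3, ...)
  tsdSeq <- if (is.null(tsd)) "" else tsd$tsdSeq
  tsdLen <- if (is.null(tsd)) 0L else tsd$tsdLen
  flank5 <- substr(c5, max(1L, nchar(c5) - tsdLen - flankLen + 1L),
                   nchar(c5) - tsdLen)
  flank3 <- substr(c3, tsdLen + 1L, min(nchar(c3), tsdLen + flankLen))
  window <- paste0(flank5, tsdSeq, flank3)
  ecrCount <- if (!is.null(ecr) && !is.null(insertionInterval))
    countEcr(insertionInterval, ecr, radius = radius) else NA_integer_
  repCtx <- "none"
  if (!is.null(repeats) && !is.null(insertionInterval) && length(repeats)) {
    if (!is(insertionInterval, "GRanges")) {
      ii <- as.list(insertionInterval)
      insertionInterval <- GenomicRanges::GRanges(as.character(ii$chrom),
        IRanges::IRanges(as.integer(ii$start), as.integer(ii$end)))
    }
    ov <- GenomicRanges::findOverlaps(insertionInterval, repeats,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      classes <- repeats$name[S4Vectors::subjectHits(ov)]
      for (cl in c("LINE", "LTR", "SINE"))
        if (cl %in% classes) { repCtx <- cl; break }
    }
  }
  new("SiteReport", name = as.character(name), tsdSeq = tsdSeq,
      tsdLen = tsdLen, flank5 = flank5, flank3 = flank3,
      gcPercent = gcWindow(window), motifHits = scanMotif(window, motif),
      ecrCount = ecrCount, repeatContext = repCtx, strand = strand)
}

#' The G/C window of a SiteReport
#' @param x a [SiteReport].
#' @return `flank5 + TSD + flank3` as a character string.
#' @export
siteWindow <- function(x) paste0(x@flank5, x@tsdSeq, x@flank3)

#' Published canid FGF4 retrocopy insertion sites
#'
#' The seven characterized FGF4 retrocopy insertion sites in canids
#' (FGF4L1-FGF4L7): genomic location, TSD sequence, 10 bp flanks, strand,
#' published G/C percentage and conserved-element count. Useful as a real
#' worked dataset for the TSD finder and window statistics.
#'
#' @return a `data.frame` with columns `name`, `chrom`, `start`, `end`,
#'   `flank5`, `tsd`, `flank3`, `strand`, `gc`, `ecr`, `method`.
#' @examples
#' sites <- fgf4InsertionSites()
#' findTsd(paste0(sites$flank5[1], sites$tsd[1]),
#'         paste0(sites$tsd[1], sites$flank3[1]))$tsdLen
#' @export
fgf4InsertionSites <- function() {
  path <- system.file("extdata", "fgf4_insertion_sites.tsv",
                      package = "retroseek", mustWork = TRUE)
  readTsv(path)
}

#' Write SiteReports as a TSV table
#'
#' Columns mirror the conventional insertion-site table: name, location,
#' sequence with the TSD delimited by brackets, strand, G/C, ECR count,
#' repeat context.
#'
#' @param reports list of [SiteReport] objects.
#' @param path output path.
#' @param locations optional character vector of location labels.
#' @return `path`, invisibly.
#' @export
writeSiteReports <- function(reports, path, locations = NULL) {
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(
      name = r@name,
      location = if (is.null(locations)) NA_character_ else locations[i],
      sequence = paste0(r@flank5, "[", r@tsdSeq, "]", r@flank3),
      tsdLen = r@tsdLen,
      strand = r@strand,
      gc = r@gcPercent,
      motifHits = length(r@motifHits),
      ecr = r@ecrCount,
      repeatContext = r@repeatContext,
      stringsAsFactors = FALSE)
  }))
  writeTsv(df, path)
}
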