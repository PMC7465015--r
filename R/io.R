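# Shared I/O adapters and coordinate-convention conversion.
#
# Internally every interval is 1-based inclusive (the convention genome
# browsers print); conversion to/from BED's 0-based half-open convention
# happens only here, at the I/O boundary.

#' Coordinate-convention converters
#'
#' 1-based inclusive internal coordinates vs BED 0-based half-open.
#' `oneToZeroStart(s)` = `s - 1`; ends are unchanged (inclusive end equals
#' half-open end). The pair of functions round-trips exactly.
#'
#' @param s 1-based start (or 0-based start for the inverse).
#' @return integer vector.
#' @examples
#' zeroToOneStart(oneToZeroStart(100)) == 100
#' @export
oneToZeroStart <- function(s) as.integer(s) - 1L

#' @rdname oneToZeroStart
#' @export
zeroToOneStart <- function(s) as.integer(s) + 1L

#' Read a BED file of intervals as GRanges
#'
#' Thin wrapper over [rtracklayer::import] that reports the file on
#' failure and validates interval sanity line by line.
#'
#' @param path BED file path.
#' @return a [GenomicRanges::GRanges] (1-based inclusive).
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path, call. = FALSE)
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "track")]
  for (i in seq_along(raw)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))) ||
        as.integer(f[3]) < as.integer(f[2]))
      stop("malformed BED line ", i, " in ", path, call. = FALSE)
  }
  tryCatch(rtracklayer::import(path, format = "BED"),
           error = function(e)
             stop("failed to parse BED ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

#' Write GRanges as BED
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedIntervals <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read paired-end alignments from a SAM file
#'
#' Converts through BAM (Rsamtools) and assembles mates into one row per
#' pair. Reads lacking a mate in the file are dropped; unmapped mates are
#' kept (`chrom` `NA`) so pairs can be classified as uninformative rather
#' than erroring.
#'
#' @param samPath path to a SAM file with valid headers.
#' @return a `data.frame` with one row per pair: `pairId`, and per mate
#'   `chrom`, `pos`, `end`, `strand`, `cigar`, `seq`, `clipLeft`,
#'   `clipRight` (soft-clip lengths).
#' @export
readPairs <- function(samPath) {
  if (!file.exists(samPath)) stop("no such SAM file: ", samPath, call. = FALSE)
  bam <- Rsamtools::asBam(samPath, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  if (n == 0L)
    return(data.frame(pairId = character(),
                      chrom1 = character(), pos1 = integer(),
                      end1 = integer(), strand1 = character(),
                      cigar1 = character(), seq1 = character(),
                      clipLeft1 = integer(), clipRight1 = integer(),
                      chrom2 = character(), pos2 = integer(),
                      end2 = integer(), strand2 = character(),
                      cigar2 = character(), seq2 = character(),
                      clipLeft2 = integer(), clipRight2 = integer(),
                      stringsAsFactors = FALSE))
  unmapped <- bitwAnd(x$flag, 0x4L) != 0L
  first <- bitwAnd(x$flag, 0x40L) != 0L
  cig <- x$cigar
  refw <- rep(NA_integer_, n)
  ok <- !is.na(cig) & !unmapped
  # fast path for clip/match-only CIGARs; general CIGARs go through
  # GenomicAlignments
  simple <- ok & grepl("^([0-9]+S)?[0-9]+M([0-9]+S)?$", cig)
  refw[simple] <- as.integer(sub("^(?:[0-9]+S)?([0-9]+)M.*$", "\\1",
                                 cig[simple], perl = TRUE))
  hard <- ok & !simple
  if (any(hard))
    refw[hard] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig[hard])
  clips <- samClipLengths(cig)
  df <- data.frame(
    qname = x$qname,
    first = first,
    chrom = ifelse(unmapped, NA_character_, as.character(x$rname)),
    pos = ifelse(unmapped, NA_integer_, x$pos),
    end = ifelse(unmapped, NA_integer_, x$pos + refw - 1L),
    strand = ifelse(unmapped, NA_character_, as.character(x$strand)),
    cigar = ifelse(is.na(cig), "*", cig),
    seq = as.character(x$seq),
    clipLeft = clips$left, clipRight = clips$right,
    stringsAsFactors = FALSE)
  m1 <- df[df$first, , drop = FALSE]
  m2 <- df[!df$first, , drop = FALSE]
  idx <- match(m1$qname, m2$qname)
  keep <- !is.na(idx)
  m1 <- m1[keep, , drop = FALSE]
  m2 <- m2[idx[keep], , drop = FALSE]
  out <- data.frame(pairId = m1$qname, stringsAsFactors = FALSE)
  for (f in c("chrom", "pos", "end", "strand", "cigar", "seq",
              "clipLeft", "clipRight")) {
    out[[paste0(f, "1")]] <- m1[[f]]
    out[[paste0(f, "2")]] <- m2[[f]]
  }
  out
}

#' Internal: soft-clip lengths at either end of a CIGAR
#' @noRd
samClipLengths <- function(cigar) {
  left <- integer(length(cigar)); right <- integer(length(cigar))
  ml <- regmatches(cigar, regexpr("^[0-9]+S", cigar))
  hasL <- grepl("^[0-9]+S", cigar)
  left[hasL] <- as.integer(sub("S", "", regmatches(cigar,
    regexpr("^[0-9]+S", cigar))))
  hasR <- grepl("[0-9]+S$", cigar)
  right[hasR] <- as.integer(sub("S", "", regmatches(cigar,
    regexpr("[0-9]+S$", cigar))))
  left[is.na(cigar)] <- 0L; right[is.na(cigar)] <- 0L
  list(left = left, right = right)
}

#' Read a population variant table from VCF
#'
#' Loads a VCF (v4.x) and expands multiallelic records into biallelic
#' variants, returning the site table used for retrocopy-variant
#' classification.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
readPopulationVcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path, call. = FALSE)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    stringsAsFactors = FALSE)
}

#' Read a gene model from an exon BED plus mRNA details
#'
#' The BED carries one line per exon (same chromosome and strand); the mRNA
#' partition is supplied alongside since BED has no notion of it. The mRNA
#' sequence may be given explicitly or spliced out of a genome FASTA.
#'
#' @param bedPath exon BED path.
#' @param utr5Len,orfLen mRNA partition lengths.
#' @param mrna spliced mRNA sequence, or `NULL` to extract from `fastaPath`.
#' @param fastaPath genome FASTA used when `mrna` is `NULL`.
#' @return a [GeneModel].
#' @export
readGeneModel <- function(bedPath, utr5Len, orfLen, mrna = NULL,
                          fastaPath = NULL) {
  gr <- readBedIntervals(bedPath)
  gr <- BiocGenerics::sort(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))[1]
  strand <- as.character(GenomicRanges::strand(gr))[1]
  if (strand == "*") strand <- "+"
  if (is.null(mrna)) {
    if (is.null(fastaPath))
      stop("provide mrna or fastaPath", call. = FALSE)
    genome <- Biostrings::readDNAStringSet(fastaPath)
    names(genome) <- sub("\\s.*$", "", names(genome))
    exSeq <- as.character(Biostrings::extractAt(genome[[chrom]],
      IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr))))
    mrna <- paste(exSeq, collapse = "")
    if (strand == "-") mrna <- revcompChar(mrna)
  }
  GeneModel(chrom, strand, GenomicRanges::start(gr),
            GenomicRanges::end(gr), utr5Len, orfLen, mrna)
}

#' TSV helpers with a fixed dialect
#'
#' @param x data.frame / path.
#' @param path file path.
#' @return `readTsv` returns a data.frame; `writeTsv` returns `path`.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
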