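#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors DataFrame
NULL

#' Accessors for GeneModel
#'
#' @param x a [GeneModel].
#' @return `geneChrom`/`geneStrand` return scalars; `exons` the exon
#'   `IRanges`; `mrnaSeq` the spliced `DNAString`; `mrnaLength` its length;
#'   `geneRange` the genomic span as a `GRanges`.
#' @name GeneModel-accessors
#' @aliases geneChrom geneStrand exons mrnaSeq mrnaLength geneRange
NULL

#' @rdname GeneModel-accessors
#' @export
geneChrom <- function(x) x@chrom

#' @rdname GeneModel-accessors
#' @export
geneStrand <- function(x) x@strand

#' @rdname GeneModel-accessors
#' @export
exons <- function(x) x@exons

#' @rdname GeneModel-accessors
#' @export
mrnaSeq <- function(x) x@mrna

#' @rdname GeneModel-accessors
#' @export
mrnaLength <- function(x) length(x@mrna)

#' @rdname GeneModel-accessors
#' @export
geneRange <- function(x) {
  GenomicRanges::GRanges(x@chrom,
    IRanges::IRanges(min(IRanges::start(x@exons)),
                     max(IRanges::end(x@exons))),
    strand = x@strand)
}

#' Sub-interval accessors (mRNA coordinates)
#' @rdname GeneModel-accessors
#' @export
utr5 <- function(x) x@utr5

#' @rdname GeneModel-accessors
#' @export
orf <- function(x) x@orf

#' @rdname GeneModel-accessors
#' @export
utr3 <- function(x) x@utr3

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel on %s(%s): %d exons, mRNA %d bp (UTR5 %d / ORF %d / UTR3 %d)\n",
              object@chrom, object@strand, length(object@exons),
              length(object@mrna), IRanges::width(object@utr5),
              IRanges::width(object@orf), IRanges::width(object@utr3)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d bp reads, insert %g +/- %g, %gx coverage, error %g, seed %d\n",
              object@readLen, object@insertMean, object@insertSd,
              object@coverage, object@errorRate, object@seed))
})

setMethod("show", "InsertionTruth", function(object) {
  cat(sprintf("InsertionTruth at %s:%d (%s), TSD %d bp, trunc5 %d, trunc3 %d, polyA %d\n",
              object@targetChrom, object@targetPos, object@strand,
              object@tsdLen, object@trunc5, object@trunc3, object@polyALen))
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosome(s), %s bp total\n",
              length(object@chroms),
              format(sum(Biostrings::width(object@chroms)), big.mark = ",")))
  show(object@gene)
})

setMethod("show", "PlantedGenome", function(object) {
  callNextMethod()
  cat(sprintf("  %d planted insertion(s)\n", length(object@truths)))
})

setMethod("show", "SiteReport", function(object) {
  cat(sprintf("SiteReport %s: TSD %d bp [%s], strand %s, G/C %.1f%%, motif hits %d, ECR %d, repeat %s\n",
              object@name, object@tsdLen, object@tsdSeq, object@strand,
              object@gcPercent, length(object@motifHits), object@ecrCount,
              object@repeatContext))
})

setMethod("show", "TruncationReport", function(object) {
  cat(sprintf("TruncationReport: trunc5 %d bp, trunc3 %d bp, ORF %s (identity %.1f%%)\n",
              object@trunc5, object@trunc3,
              if (object@orfIntact) "intact" else "disrupted",
              object@identity))
})

#' Project mRNA positions onto the genome (and back)
#'
#' Maps 1-based spliced-mRNA coordinates to 1-based genomic coordinates
#' through the exon structure, honouring gene strand: on a `-` strand gene,
#' mRNA position 1 is the last base of the last exon interval.
#'
#' @param gene a [GeneModel].
#' @param pos integer vector of mRNA positions (`mrnaToGenomic`) or genomic
#'   positions (`genomicToMrna`).
#' @return integer vector of projected positions; `genomicToMrna` returns
#'   `NA` for intronic/outside positions.
#' @examples
#' gm <- GeneModel("c", "+", c(11, 31), c(20, 40), 4, 12,
#'                 paste(rep("ACGTA", 4), collapse = ""))
#' mrnaToGenomic(gm, c(1, 10, 11, 20))
#' genomicToMrna(gm, c(11, 20, 25, 31))
#' @export
mrnaToGenomic <- function(gene, pos) {
  pos <- as.integer(pos)
  mlen <- mrnaLength(gene)
  if (any(pos < 1L | pos > mlen))
    stop("mRNA position out of range 1..", mlen, call. = FALSE)
  w <- IRanges::width(gene@exons)
  if (gene@strand == "+") {
    cum <- cumsum(c(0L, w))
    idx <- findInterval(pos, cum[-1L], left.open = TRUE) + 1L
    IRanges::start(gene@exons)[idx] + (pos - cum[idx] - 1L)
  } else {
    # mRNA runs along the reverse strand: exon order reversed, within-exon
    # positions count down from exon end
    wr <- rev(w)
    cum <- cumsum(c(0L, wr))
    idx <- findInterval(pos, cum[-1L], left.open = TRUE) + 1L
    exIdx <- length(w) - idx + 1L
    IRanges::end(gene@exons)[exIdx] - (pos - cum[idx] - 1L)
  }
}

#' @rdname mrnaToGenomic
#' @export
genomicToMrna <- function(gene, pos) {
  pos <- as.integer(pos)
  s <- IRanges::start(gene@exons); e <- IRanges::end(gene@exons)
  w <- IRanges::width(gene@exons)
  out <- rep(NA_integer_, length(pos))
  for (k in seq_along(s)) {
    inEx <- !is.na(pos) & pos >= s[k] & pos <= e[k]
    if (!any(inEx)) next
    if (gene@strand == "+") {
      before <- if (k > 1L) sum(w[seq_len(k - 1L)]) else 0L
      out[inEx] <- before + (pos[inEx] - s[k] + 1L)
    } else {
      after <- if (k < length(w)) sum(w[seq(k + 1L, length(w))]) else 0L
      out[inEx] <- after + (e[k] - pos[inEx] + 1L)
    }
  }
  out
}

#' Exon index of mRNA positions
#'
#' @param gene a [GeneModel].
#' @param pos mRNA positions.
#' @return integer exon indices (in genomic order).
#' @export
exonOfMrnaPos <- function(gene, pos) {
  pos <- as.integer(pos)
  w <- IRanges::width(gene@exons)
  if (gene@strand == "+") {
    cum <- cumsum(w)
    findInterval(pos, cum, left.open = TRUE) + 1L
  } else {
    cum <- cumsum(rev(w))
    idx <- findInterval(pos, cum, left.open = TRUE) + 1L
    length(w) - idx + 1L
  }
}

#' mRNA region (UTR5/ORF/UTR3) of mRNA positions
#'
#' @param gene a [GeneModel].
#' @param pos mRNA positions.
#' @return character vector in `c("UTR5", "ORF", "UTR3")`.
#' @export
mrnaRegion <- function(gene, pos) {
  pos <- as.integer(pos)
  ifelse(pos <= IRanges::end(gene@utr5), "UTR5",
         ifelse(pos <= IRanges::end(gene@orf), "ORF", "UTR3"))
}
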