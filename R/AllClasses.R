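#' @import methods
#' @importFrom IRanges IRanges start end width
#' @importFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
NULL

#' Parental gene model
#'
#' Describes the parental gene of a retrocopy family: its genomic location,
#' ordered exon intervals, the spliced mRNA sequence, and the 5' UTR / ORF /
#' 3' UTR partition of that mRNA. All genomic coordinates are 1-based
#' inclusive; `utr5`, `orf` and `utr3` are intervals in mRNA (spliced)
#' coordinates.
#'
#' @slot chrom chromosome name.
#' @slot strand gene strand, `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon genomic intervals, sorted,
#'   non-overlapping.
#' @slot utr5,orf,utr3 single-interval [IRanges::IRanges] in mRNA
#'   coordinates; together they partition `1..mrnaLength`.
#' @slot mrna [Biostrings::DNAString] spliced mRNA (coding-strand sequence).
#'
#' @examples
#' gm <- GeneModel("chrA", "+", exonStarts = c(101, 501, 901),
#'                 exonEnds = c(200, 560, 1100),
#'                 utr5Len = 50, orfLen = 120,
#'                 mrna = paste(rep("ACGT", 90), collapse = ""))
#' mrnaLength(gm)
#' @export GeneModel
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    chrom  = "character",
    strand = "character",
    exons  = "IRanges",
    utr5   = "IRanges",
    orf    = "IRanges",
    utr3   = "IRanges",
    mrna   = "DNAString"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be length 1")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) < 1L) msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    if (is.unsorted(IRanges::start(ex), strictly = TRUE))
      msg <- c(msg, "exons must be sorted by start")
    if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  mlen <- length(object@mrna)
  if (mlen != sum(IRanges::width(ex)))
    msg <- c(msg, "mRNA length must equal the summed exon lengths")
  u5 <- object@utr5; orf <- object@orf; u3 <- object@utr3
  if (length(u5) != 1L || length(orf) != 1L || length(u3) != 1L) {
    msg <- c(msg, "utr5, orf and utr3 must each be a single interval")
  } else {
    if (IRanges::start(u5) != 1L ||
        IRanges::start(orf) != IRanges::end(u5) + 1L ||
        IRanges::start(u3) != IRanges::end(orf) + 1L ||
        IRanges::end(u3) != mlen)
      msg <- c(msg, "utr5 + orf + utr3 must partition the mRNA")
    if (IRanges::width(orf) %% 3L != 0L)
      msg <- c(msg, "ORF length must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exonStarts,exonEnds integer vectors of exon genomic bounds
#'   (1-based inclusive).
#' @param utr5Len,orfLen lengths in bp of the 5' UTR and ORF on the mRNA;
#'   the 3' UTR is the remainder.
#' @param mrna spliced mRNA sequence (character or `DNAString`).
#' @rdname GeneModel-class
#' @export
GeneModel <- function(chrom, strand, exonStarts, exonEnds, utr5Len, orfLen,
                      mrna) {
  if (is.character(mrna)) mrna <- Biostrings::DNAString(checkDna(mrna, "mrna"))
  mlen <- length(mrna)
  new("GeneModel",
      chrom = as.character(chrom), strand = strand,
      exons = IRanges::IRanges(start = as.integer(exonStarts),
                               end = as.integer(exonEnds)),
      utr5 = IRanges::IRanges(1L, as.integer(utr5Len)),
      orf  = IRanges::IRanges(as.integer(utr5Len) + 1L,
                              as.integer(utr5Len + orfLen)),
      utr3 = IRanges::IRanges(as.integer(utr5Len + orfLen) + 1L, mlen),
      mrna = mrna)
}

#' Simulation configuration
#'
#' Parameters of the paired-end library simulated by
#' [simulateAlignments()]. Defaults model a modern short-read library:
#' 150 bp reads, 400 +/- 50 bp inserts. A fixed `seed` makes the simulator
#' byte-deterministic.
#'
#' @slot readLen read length, bp.
#' @slot insertMean,insertSd fragment (insert) size mean and SD, bp.
#' @slot coverage fold sequence coverage.
#' @slot errorRate per-base substitution error rate.
#' @slot seed integer RNG seed.
#' @export SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
  representation(readLen = "integer", insertMean = "numeric",
                 insertSd = "numeric", coverage = "numeric",
                 errorRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@readLen < 20L) msg <- c(msg, "readLen must be >= 20")
  if (object@insertMean <= 0) msg <- c(msg, "insertMean must be positive")
  if (object@insertSd < 0) msg <- c(msg, "insertSd must be >= 0")
  if (object@insertMean <= 2 * object@readLen)
    msg <- c(msg, "insertMean must exceed 2 * readLen")
  if (object@coverage <= 0) msg <- c(msg, "coverage must be positive")
  if (object@errorRate < 0 || object@errorRate > 0.2)
    msg <- c(msg, "errorRate must be in [0, 0.2]")
  if (length(msg)) msg else TRUE
})

#' @param readLen,insertMean,insertSd,coverage,errorRate,seed see slots.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(readLen = 150L, insertMean = 400, insertSd = 50,
                      coverage = 20, errorRate = 0.001, seed = 1L) {
  new("SimConfig", readLen = as.integer(readLen), insertMean = insertMean,
      insertSd = insertSd, coverage = coverage, errorRate = errorRate,
      seed = as.integer(seed))
}

#' Planted insertion truth
#'
#' Ground-truth description of one planted retrocopy insertion: where it
#' goes, its target site duplication length, orientation, UTR truncations
#' and polyA-tail length. The insertion allele is
#' `TSD + oriented(truncated mRNA + polyA) + TSD-copy`, mirroring the
#' structure produced by L1 target-primed reverse transcription.
#'
#' @slot targetChrom insertion chromosome.
#' @slot targetPos 1-based position; the insertion lands immediately after
#'   this base, and the TSD is the `tsdLen` bases ending here.
#' @slot tsdLen TSD length, bp (>= 0; 0 means no duplication).
#' @slot strand orientation of the retrocopy relative to the reference.
#' @slot trunc5,trunc3 bp removed from the mRNA 5'/3' ends.
#' @slot polyALen length of the templated polyA tail, bp.
#' @export InsertionTruth
#' @exportClass InsertionTruth
setClass("InsertionTruth",
  representation(targetChrom = "character", targetPos = "integer",
                 tsdLen = "integer", strand = "character",
                 trunc5 = "integer", trunc3 = "integer",
                 polyALen = "integer"))

setValidity("InsertionTruth", function(object) {
  msg <- character()
  if (object@tsdLen < 0L) msg <- c(msg, "tsdLen must be >= 0")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  if (object@trunc5 < 0L || object@trunc3 < 0L)
    msg <- c(msg, "truncations must be >= 0")
  if (object@polyALen < 0L) msg <- c(msg, "polyALen must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param targetChrom,targetPos,tsdLen,strand,trunc5,trunc3,polyALen see slots.
#' @rdname InsertionTruth-class
#' @export
InsertionTruth <- function(targetChrom, targetPos, tsdLen = 13L,
                           strand = "+", trunc5 = 0L, trunc3 = 0L,
                           polyALen = 50L) {
  new("InsertionTruth", targetChrom = as.character(targetChrom),
      targetPos = as.integer(targetPos), tsdLen = as.integer(tsdLen),
      strand = strand, trunc5 = as.integer(trunc5),
      trunc3 = as.integer(trunc3), polyALen = as.integer(polyALen))
}

#' Synthetic genome with a parental gene
#'
#' Reference chromosome sequences plus the [GeneModel] embedded in them.
#' Produced by [buildGenome()].
#'
#' @slot chroms [Biostrings::DNAStringSet] of reference chromosomes.
#' @slot gene the parental [GeneModel].
#' @export GenomeModel
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(chroms = "DNAStringSet", gene = "GeneModel"))

#' @param chroms named `DNAStringSet`.
#' @param gene a `GeneModel` located on one of `chroms`.
#' @rdname GenomeModel-class
#' @export
GenomeModel <- function(chroms, gene) {
  new("GenomeModel", chroms = chroms, gene = gene)
}

setValidity("GenomeModel", function(object) {
  msg <- character()
  if (is.null(names(object@chroms)) || anyDuplicated(names(object@chroms)))
    msg <- c(msg, "chromosomes must have unique names")
  g <- object@gene
  if (!g@chrom %in% names(object@chroms)) {
    msg <- c(msg, "gene chromosome not present in genome")
  } else if (max(IRanges::end(g@exons)) > length(object@chroms[[g@chrom]])) {
    msg <- c(msg, "gene exons exceed chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Genome with planted retrocopy insertions
#'
#' Extends [GenomeModel] with the mutated ("sample") chromosome sequences
#' carrying planted retrocopies, the per-insertion [InsertionTruth] records
#' and the reconstructed insertion-allele sequences. The `chroms` slot keeps
#' the retrocopy-free reference that reads are aligned against.
#'
#' @slot mutated `DNAStringSet`: sample chromosomes carrying the insertions.
#' @slot truths list of [InsertionTruth].
#' @slot alleles `DNAStringSet` of insertion alleles
#'   (TSD + insert + TSD copy), one per truth.
#' @export
#' @exportClass PlantedGenome
setClass("PlantedGenome", contains = "GenomeModel",
  representation(mutated = "DNAStringSet", truths = "list",
                 alleles = "DNAStringSet"))

setValidity("PlantedGenome", function(object) {
  msg <- character()
  if (length(object@truths) != length(object@alleles))
    msg <- c(msg, "one allele per truth required")
  if (!all(vapply(object@truths, is, TRUE, "InsertionTruth")))
    msg <- c(msg, "truths must be InsertionTruth objects")
  if (length(msg)) msg else TRUE
})

#' Insertion-site characterization report
#'
#' Breakpoint-level description of one retrocopy insertion site: the target
#' site duplication, 10 bp flanks, G/C content of the flank+TSD+flank
#' window, L1 endonuclease motif hits, conserved elements within a radius,
#' and repeat context. Sequences are reported on the reference forward
#' strand; `strand` records the retrocopy orientation separately.
#'
#' @slot name site label.
#' @slot tsdSeq TSD sequence ("" when none detected).
#' @slot tsdLen TSD length, bp.
#' @slot flank5,flank3 10 bp of reference sequence on either side of the TSD.
#' @slot gcPercent G/C percentage of `flank5 + TSD + flank3`, one decimal.
#' @slot motifHits integer vector of 1-based forward-strand motif start
#'   offsets within the window.
#' @slot ecrCount conserved elements within the query radius.
#' @slot repeatContext `"LINE"`, `"LTR"`, `"SINE"` or `"none"`.
#' @slot strand retrocopy orientation.
#' @export
#' @exportClass SiteReport
setClass("SiteReport",
  representation(name = "character", tsdSeq = "character", tsdLen = "integer",
                 flank5 = "character", flank3 = "character",
                 gcPercent = "numeric", motifHits = "integer",
                 ecrCount = "integer", repeatContext = "character",
                 strand = "character"))

setValidity("SiteReport", function(object) {
  msg <- character()
  if (nchar(object@tsdSeq) != object@tsdLen)
    msg <- c(msg, "tsdSeq length must equal tsdLen")
  if (isTRUE(object@ecrCount < 0L)) msg <- c(msg, "ecrCount must be >= 0")
  if (!object@repeatContext %in% c("LINE", "LTR", "SINE", "none"))
    msg <- c(msg, "invalid repeatContext")
  if (length(msg)) msg else TRUE
})

#' UTR truncation report
#'
#' How much of the parental mRNA is missing from a retrocopy at either end,
#' and whether the ORF is intact (fully covered, no indel, no premature
#' stop).
#'
#' @slot trunc5,trunc3 bp of mRNA missing from the 5'/3' ends.
#' @slot orfIntact logical.
#' @slot identity alignment percent identity against the parental mRNA.
#' @export
#' @exportClass TruncationReport
setClass("TruncationReport",
  representation(trunc5 = "integer", trunc3 = "integer",
                 orfIntact = "logical", identity = "numeric"))
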