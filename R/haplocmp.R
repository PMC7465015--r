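# Retrocopy-vs-parental comparison: align a retrocopy to the parental
# mRNA, call the differences, and decide for each whether it is carried by
# a parental-gene haplotype segregating in the population or is specific
# to the retrocopy (i.e. arose after retrotransposition).

VARIANT_CLASSES <- c("HAPLOTYPE_SHARED", "RETROCOPY_SPECIFIC", "UNKNOWN")

#' Internal: end-free alignment of a retrocopy against the parental mRNA
#'
#' Pattern (retrocopy) global, subject (mRNA) local: mRNA overhangs are
#' free, so UTR truncations surface as unaligned mRNA ends. Scoring
#' defaults: match 1, mismatch -2; affine gaps cost 5 for the first base
#' and 1 per additional base (gapOpening 4 + gapExtension 1 in the
#' Biostrings parameterization).
#' @noRd
alignToMrna <- function(retro, gene, minIdentity = 90,
                        match = 1, mismatch = -2,
                        gapOpening = 4, gapExtension = 1) {
  mrna <- as.character(mrnaSeq(gene))
  if (nchar(retro) < 10L) stop("retro sequence too short", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(retro),
    subject = Biostrings::DNAString(mrna),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = gapOpening, gapExtension = gapExtension)
  identity <- Biostrings::pid(aln, type = "PID1")
  if (identity < minIdentity)
    stop(sprintf(
      "alignment identity %.1f%% < %g%%: not a retrocopy of this gene",
      identity, minIdentity), call. = FALSE)
  list(
    aln = aln,
    identity = identity,
    subjectRange = IRanges::IRanges(
      BiocGenerics::start(Biostrings::subject(aln)),
      BiocGenerics::end(Biostrings::subject(aln))),
    patternAligned = strsplit(as.character(
      Biostrings::alignedPattern(aln)), "")[[1]],
    subjectAligned = strsplit(as.character(
      Biostrings::alignedSubject(aln)), "")[[1]])
}

#' Align a retrocopy to the parental mRNA and call differences
#'
#' Calls one variant per difference between the retrocopy and the parental
#' mRNA: SNVs, insertions and deletions. Positions are reported both on
#' the mRNA and projected to parental-locus genomic coordinates through
#' the exon map; each variant is assigned to UTR5/ORF/UTR3. Indels are
#' left-normalized (VCF convention, with the preceding base as anchor) so
#' population-table lookups are well defined. A trailing polyA run and a
#' flanking TSD are expected to be stripped beforehand (see
#' `stripPolyA`).
#'
#' @param retroSeq retrocopy sequence on the mRNA strand, >= 200 bp.
#' @param gene the parental [GeneModel].
#' @param minIdentity rejection threshold (percent identity).
#' @param stripPolyA strip a trailing A-run (>= 5 bp) before aligning so
#'   the tail is not called as an insertion.
#' @return a `data.frame` of variants: `mrnaPos`, `genomicPos`, `chrom`,
#'   `ref`, `alt`, `kind` (`SNV`/`ins`/`del`), `region`. SNV positions are
#'   the changed base; indel positions are the anchor base before the
#'   event, VCF-style.
#' @examples
#' gm <- GeneModel("c", "+", c(1, 301), c(250, 550), 100, 300,
#'                 mrna = paste(rep("ACGTT", 100), collapse = ""))
#' nrow(alignAndCall(as.character(mrnaSeq(gm)), gm))  # 0
#' @export
alignAndCall <- function(retroSeq, gene, minIdentity = 90,
                         stripPolyA = TRUE) {
  retro <- checkDna(retroSeq, "retroSeq")
  if (stripPolyA) retro <- sub("A{5,}$", "", retro)
  if (nchar(retro) < 200L)
    stop("retro sequence must be >= 200 bp", call. = FALSE)
  a <- alignToMrna(retro, gene, minIdentity = minIdentity)
  p <- a$patternAligned; s <- a$subjectAligned
  off <- IRanges::start(a$subjectRange) - 1L
  sPos <- cumsum(s != "-") + off           # mRNA position per column
  mrnaChar <- strsplit(as.character(mrnaSeq(gene)), "")[[1]]

  vars <- list()
  addVar <- function(mrnaPos, ref, alt, kind) {
    vars[[length(vars) + 1L]] <<- data.frame(
      mrnaPos = mrnaPos, ref = ref, alt = alt, kind = kind,
      stringsAsFactors = FALSE)
  }
  # SNVs
  snv <- which(p != "-" & s != "-" & p != s)
  for (i in snv) addVar(sPos[i], s[i], p[i], "SNV")
  # deletions (gap in pattern): bases missing from the retrocopy
  i <- 1L; n <- length(p)
  while (i <= n) {
    if (p[i] == "-" && s[i] != "-") {
      j <- i
      while (j < n && p[j + 1L] == "-" && s[j + 1L] != "-") j <- j + 1L
      delStart <- sPos[i]; delEnd <- sPos[j]
      norm <- leftNormalizeIndel(mrnaChar, delStart, delEnd, inserted = NULL)
      addVar(norm$anchor, norm$ref, norm$alt, "del")
      i <- j + 1L
    } else if (s[i] == "-" && p[i] != "-") {
      j <- i
      while (j < n && s[j + 1L] == "-" && p[j + 1L] != "-") j <- j + 1L
      insSeq <- paste(p[i:j], collapse = "")
      anchorPos <- if (i > 1L) sPos[i - 1L] else off  # base before insertion
      norm <- leftNormalizeIndel(mrnaChar, anchorPos + 1L, anchorPos,
                                 inserted = insSeq)
      addVar(norm$anchor, norm$ref, norm$alt, "ins")
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(vars)) {
    out <- data.frame(mrnaPos = integer(), genomicPos = integer(),
                      chrom = character(), ref = character(),
                      alt = character(), kind = character(),
                      region = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, vars)
  out <- out[order(out$mrnaPos), , drop = FALSE]
  out$genomicPos <- mrnaToGenomic(gene, out$mrnaPos)
  out$chrom <- geneChrom(gene)
  out$region <- mrnaRegion(gene, out$mrnaPos)
  if (geneStrand(gene) == "-") {
    # project alleles to the genomic forward strand
    out$ref <- vapply(out$ref, revcompChar, "")
    out$alt <- vapply(out$alt, revcompChar, "")
  }
  rownames(out) <- NULL
  out[, c("mrnaPos", "genomicPos", "chrom", "ref", "alt", "kind", "region")]
}

#' Internal: left-normalize an indel and express it VCF-style
#'
#' Shifts a deletion `[delStart, delEnd]` (or an insertion of `inserted`
#' before `delStart`) left while the preceding base equals the last base
#' of the event, then anchors on the base before the event.
#' @noRd
leftNormalizeIndel <- function(seqChar, delStart, delEnd, inserted = NULL) {
  if (is.null(inserted)) {               # deletion
    while (delStart > 1L &&
           seqChar[delStart - 1L] == seqChar[delEnd]) {
      delStart <- delStart - 1L; delEnd <- delEnd - 1L
    }
    anchor <- max(delStart - 1L, 1L)
    if (delStart == 1L) {  # no base before: anchor on the base after
      ref <- paste(seqChar[seq(delStart, delEnd + 1L)], collapse = "")
      alt <- seqChar[delEnd + 1L]
      anchor <- 1L
    } else {
      ref <- paste(seqChar[seq(anchor, delEnd)], collapse = "")
      alt <- seqChar[anchor]
    }
    list(anchor = anchor, ref = ref, alt = alt)
  } else {                               # insertion before position delStart
    ins <- strsplit(inserted, "")[[1]]
    pos <- delStart                      # insertion sits before seq[pos]
    while (pos > 1L && seqChar[pos - 1L] == ins[length(ins)]) {
      ins <- c(ins[length(ins)], ins[-length(ins)])
      pos <- pos - 1L
    }
    anchor <- max(pos - 1L, 1L)
    if (pos == 1L) {
      ref <- seqChar[1L]
      alt <- paste(c(ins, seqChar[1L]), collapse = "")
      anchor <- 1L
    } else {
      ref <- seqChar[anchor]
      alt <- paste(c(seqChar[anchor], ins), collapse = "")
    }
    list(anchor = anchor, ref = ref, alt = alt)
  }
}

#' Classify retrocopy variants against a population variant table
#'
#' A variant is `HAPLOTYPE_SHARED` when the identical allele (position,
#' ref and alt) segregates at the parental locus in the population
#' table -- the retrocopy difference is then explained by the parental
#' haplotype it was copied from. Variants absent from the table (or with a
#' different alt at the same position) are `RETROCOPY_SPECIFIC`,
#' i.e. candidate post-insertion mutations. Allele identity, not mere
#' positional overlap, is required.
#'
#' @param variants variant table from [alignAndCall()].
#' @param populationVcf a VCF path or the `data.frame` from
#'   [readPopulationVcf()].
#' @return `variants` with a `classification` column added.
#' @export
classifyVariants <- function(variants, populationVcf) {
  pop <- if (is.character(populationVcf)) readPopulationVcf(populationVcf)
         else populationVcf
  if (nrow(variants) == 0L) {
    variants$classification <- character(0)
    return(variants)
  }
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  popKeys <- if (nrow(pop)) key(pop$chrom, pop$pos, pop$ref, pop$alt)
             else character(0)
  mine <- key(variants$chrom, variants$genomicPos, variants$ref,
              variants$alt)
  variants$classification <- ifelse(mine %in% popKeys,
                                    "HAPLOTYPE_SHARED",
                                    "RETROCOPY_SPECIFIC")
  variants$classification[is.na(variants$genomicPos)] <- "UNKNOWN"
  variants
}

#' Match a retrocopy to its source parental haplotype
#'
#' Given phased parental haplotypes over the variant positions, finds the
#' haplotype(s) whose alleles disagree with the retrocopy at the fewest
#' positions. The retrocopy carries its called alt allele at each of its
#' variant positions and the reference allele at every other position
#' under comparison.
#'
#' @param variants variant table from [alignAndCall()] (the retrocopy's
#'   differences from the reference mRNA).
#' @param haplotypes long-format `data.frame` with columns `haplotype`,
#'   `pos` (genomic), `allele`.
#' @param refAlleles named character vector giving the reference allele at
#'   each haplotype-table position (names are positions). Defaults to the
#'   alleles implied by `variants$ref` where available.
#' @return a list: `best` (character vector of best haplotype ids, all
#'   ties), `mismatches` (their mismatch count), `table` (per-haplotype
#'   counts); or classification `UNKNOWN` (with a warning) when no
#'   haplotype covers all compared positions.
#' @export
haplotypeMatch <- function(variants, haplotypes, refAlleles = NULL) {
  stopifnot(all(c("haplotype", "pos", "allele") %in% names(haplotypes)))
  positions <- sort(unique(c(haplotypes$pos, variants$genomicPos)))
  retroAllele <- vapply(positions, function(p) {
    hit <- which(variants$genomicPos == p)
    if (length(hit)) variants$alt[hit[1L]]
    else if (!is.null(refAlleles) && as.character(p) %in% names(refAlleles))
      unname(refAlleles[as.character(p)])
    else NA_character_
  }, "")
  # non-variant positions whose reference allele was not supplied cannot
  # be compared and are dropped; variant positions always remain
  drop <- is.na(retroAllele)
  positions <- positions[!drop]
  retroAllele <- retroAllele[!drop]
  if (!length(positions)) {
    warning("no comparable positions between variants and haplotype table")
    return(list(best = character(0), mismatches = NA_integer_,
                table = data.frame(), classification = "UNKNOWN"))
  }
  ids <- unique(haplotypes$haplotype)
  counts <- vapply(ids, function(h) {
    hap <- haplotypes[haplotypes$haplotype == h, , drop = FALSE]
    al <- hap$allele[match(positions, hap$pos)]
    if (anyNA(al)) return(NA_integer_)
    sum(al != retroAllele)
  }, 1L)
  if (all(is.na(counts))) {
    warning("no haplotype covers all compared positions")
    return(list(best = character(0), mismatches = NA_integer_,
                table = data.frame(haplotype = ids, mismatches = counts),
                classification = "UNKNOWN"))
  }
  best <- ids[!is.na(counts) & counts == min(counts, na.rm = TRUE)]
  list(best = best, mismatches = min(counts, na.rm = TRUE),
       table = data.frame(haplotype = ids, mismatches = counts,
                          stringsAsFactors = FALSE),
       classification = "OK")
}

#' Summarize a retrocopy's variants
#'
#' @param variants classified variant table.
#' @return one-row `data.frame`: counts per kind, per region, and per
#'   classification.
#' @export
summarizeVariants <- function(variants) {
  data.frame(
    nVariants = nrow(variants),
    nSNV = sum(variants$kind == "SNV"),
    nIns = sum(variants$kind == "ins"),
    nDel = sum(variants$kind == "del"),
    nUTR5 = sum(variants$region == "UTR5"),
    nORF = sum(variants$region == "ORF"),
    nUTR3 = sum(variants$region == "UTR3"),
    nHaplotypeShared = sum(variants$classification == "HAPLOTYPE_SHARED"),
    nRetrocopySpecific = sum(variants$classification ==
                               "RETROCOPY_SPECIFIC"),
    stringsAsFactors = FALSE)
}
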