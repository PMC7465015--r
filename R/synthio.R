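# Synthetic genomes, planted retrocopy insertions, and simulated paired-end
# alignments with per-pair truth labels.
#
# Alignments are produced by construction rather than by running an aligner:
# every read drawn from the mutated (insertion-carrying) genome is projected
# back onto the retrocopy-free reference exactly the way a gapped aligner
# would place it -- retrocopy-internal reads onto the parental exons,
# junction-crossing reads soft-clipped at the junction -- so the detector
# consumes standard SAM while the truth of every pair stays known.

#' Build a synthetic genome containing a multi-exon parental gene
#'
#' Generates random chromosome sequences and embeds a spliced gene whose
#' exon/intron structure is given by lengths (or by explicit intervals).
#' The default gene echoes a compact growth-factor locus: three exons
#' totalling a 3.2 kb mRNA with a short ORF and a long 3' UTR.
#'
#' @param config a [SimConfig]; only its `seed` is used here.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param geneChrom,geneStart chromosome and 1-based start of exon 1.
#' @param exonLengths,intronLengths integer vectors defining the gene body
#'   (`length(intronLengths) == length(exonLengths) - 1`). At least two
#'   exons are required so exon-junction signals exist.
#' @param exonStarts,exonEnds optional explicit exon intervals overriding
#'   the length-based layout (validated: sorted, non-overlapping).
#' @param utr5Len,orfLen mRNA partition; 3' UTR is the remainder.
#' @param strand gene strand.
#' @return a [GenomeModel].
#' @examples
#' g <- buildGenome(SimConfig(seed = 7), chromLengths = c(chrA = 60000),
#'                  geneStart = 20001)
#' mrnaLength(g@gene)
#' @export
buildGenome <- function(config = SimConfig(),
                        chromLengths = c(chrA = 200000L, chrB = 200000L),
                        geneChrom = names(chromLengths)[1L],
                        geneStart = 50001L,
                        exonLengths = c(476L, 104L, 2620L),
                        intronLengths = c(1300L, 700L),
                        exonStarts = NULL, exonEnds = NULL,
                        utr5Len = 480L, orfLen = 621L,
                        strand = "+") {
  stopifnot(is(config, "SimConfig"))
  if (is.null(exonStarts)) {
    if (length(exonLengths) < 2L)
      stop("at least 2 exons are required", call. = FALSE)
    if (length(intronLengths) != length(exonLengths) - 1L)
      stop("need one intron length per internal junction", call. = FALSE)
    exonStarts <- geneStart +
      cumsum(c(0L, exonLengths[-length(exonLengths)] + intronLengths))
    exonEnds <- exonStarts + exonLengths - 1L
  }
  set.seed(config@seed)
  chroms <- Biostrings::DNAStringSet(vapply(chromLengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1)))
  names(chroms) <- names(chromLengths)
  if (!geneChrom %in% names(chroms))
    stop("geneChrom not among chromLengths names", call. = FALSE)
  if (max(exonEnds) > length(chroms[[geneChrom]]))
    stop("gene exons exceed chromosome bounds", call. = FALSE)
  if (is.unsorted(exonStarts, strictly = TRUE))
    stop("exon list must be sorted by start", call. = FALSE)
  if (any(exonStarts[-1L] <= exonEnds[-length(exonEnds)]))
    stop("exon intervals must be non-overlapping", call. = FALSE)
  exonIv <- IRanges::IRanges(as.integer(exonStarts), as.integer(exonEnds))
  exonSeqs <- as.character(Biostrings::extractAt(chroms[[geneChrom]],
                                                 exonIv))
  mrna <- paste(exonSeqs, collapse = "")
  if (strand == "-") mrna <- revcompChar(mrna)
  # make the annotated ORF a genuine open reading frame (start codon,
  # sense codons, single terminal stop) so coding-intactness is meaningful
  mrna <- plantOrf(mrna, as.integer(utr5Len), as.integer(orfLen))
  # write the (possibly edited) spliced sequence back into the chromosome
  mrnaGenomic <- if (strand == "-") revcompChar(mrna) else mrna
  cutpoints <- cumsum(IRanges::width(exonIv))
  pieces <- substring(mrnaGenomic, c(1L, cutpoints[-length(cutpoints)] + 1L),
                      cutpoints)
  chroms[[geneChrom]] <- Biostrings::replaceAt(chroms[[geneChrom]], exonIv,
                                               pieces)
  gene <- GeneModel(geneChrom, strand, exonStarts, exonEnds,
                    utr5Len, orfLen, mrna)
  GenomeModel(chroms, gene)
}

#' Internal: rewrite the ORF region of an mRNA into a real reading frame
#'
#' ATG, random sense codons, one terminal stop; uses the current RNG
#' stream so the result stays seed-deterministic.
#' @noRd
plantOrf <- function(mrna, utr5Len, orfLen) {
  stopCodons <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  allCodons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(allCodons, stopCodons)
  nCodon <- orfLen %/% 3L
  body <- if (nCodon > 2L)
    paste(sample(sense, nCodon - 2L, replace = TRUE), collapse = "") else ""
  orfSeq <- paste0("ATG", body, sample(stopCodons, 1L))
  orfSeq <- substr(orfSeq, 1L, orfLen)
  paste0(substr(mrna, 1L, utr5Len), orfSeq,
         substr(mrna, utr5Len + orfLen + 1L, nchar(mrna)))
}

#' Insertion allele sequence for a truth record
#'
#' `TSD + oriented(truncated mRNA + polyA) + TSD copy`, with the TSD taken
#' from the reference at `[targetPos - tsdLen + 1, targetPos]`.
#' @noRd
buildAllele <- function(refChromSeq, gene, truth) {
  mlen <- mrnaLength(gene)
  if (truth@trunc5 + truth@trunc3 >= mlen)
    stop("truncations remove the whole mRNA", call. = FALSE)
  insMrna <- as.character(mrnaSeq(gene))
  insMrna <- substr(insMrna, truth@trunc5 + 1L, mlen - truth@trunc3)
  body <- paste0(insMrna, strrep("A", truth@polyALen))
  if (truth@strand == "-") body <- revcompChar(body)
  tsd <- if (truth@tsdLen > 0L) {
    as.character(Biostrings::subseq(refChromSeq,
      truth@targetPos - truth@tsdLen + 1L, truth@targetPos))
  } else ""
  list(tsd = tsd, body = body, allele = paste0(tsd, body, tsd))
}

#' Plant a retrocopy insertion into a genome
#'
#' Inserts `oriented(truncated mRNA + polyA) + TSD copy` immediately after
#' `targetPos`, so that the `tsdLen` reference bases ending at `targetPos`
#' appear duplicated on both sides of the insert. Truth coordinates are
#' always in reference coordinates; planting several insertions (repeated
#' calls) rebuilds the mutated chromosomes from the reference each time.
#'
#' @param genome a [GenomeModel] or [PlantedGenome].
#' @param truth an [InsertionTruth]; `targetPos` must lie outside the
#'   parental gene span and inside the chromosome.
#' @return a [PlantedGenome].
#' @examples
#' g <- buildGenome(SimConfig(seed = 3), c(chrA = 30000, chrB = 20000),
#'                  geneStart = 10001)
#' p <- plantRetrocopy(g, InsertionTruth("chrB", 5000, tsdLen = 13))
#' insertionAlleles(p)
#' @export
plantRetrocopy <- function(genome, truth) {
  stopifnot(is(genome, "GenomeModel"), is(truth, "InsertionTruth"))
  gene <- genome@gene
  if (!truth@targetChrom %in% names(genome@chroms))
    stop("unknown target chromosome", call. = FALSE)
  chromLen <- length(genome@chroms[[truth@targetChrom]])
  if (truth@targetPos - truth@tsdLen + 1L < 1L ||
      truth@targetPos >= chromLen)
    stop("target position out of chromosome bounds", call. = FALSE)
  gr <- geneRange(gene)
  if (truth@targetChrom == geneChrom(gene) &&
      truth@targetPos >= GenomicRanges::start(gr) &&
      truth@targetPos <= GenomicRanges::end(gr))
    stop("target position lies inside the parental gene", call. = FALSE)
  truths <- if (is(genome, "PlantedGenome")) c(genome@truths, truth)
            else list(truth)
  # order by (chrom, pos) and rebuild all mutated chromosomes from reference
  ord <- order(vapply(truths, slot, "", "targetChrom"),
               vapply(truths, slot, 1L, "targetPos"))
  truths <- truths[ord]
  pos <- vapply(truths, slot, 1L, "targetPos")
  chr <- vapply(truths, slot, "", "targetChrom")
  if (anyDuplicated(data.frame(chr, pos)))
    stop("duplicate insertion position", call. = FALSE)
  mutated <- genome@chroms
  alleles <- character(length(truths))
  for (cn in unique(chr)) {
    idx <- which(chr == cn)
    refSeq <- genome@chroms[[cn]]
    pieces <- character(0)
    prev <- 1L
    for (i in idx) {
      tr <- truths[[i]]
      al <- buildAllele(refSeq, gene, tr)
      alleles[i] <- al$allele
      pieces <- c(pieces,
                  as.character(Biostrings::subseq(refSeq, prev, tr@targetPos)),
                  al$body, al$tsd)
      prev <- tr@targetPos + 1L
    }
    pieces <- c(pieces, as.character(Biostrings::subseq(refSeq, prev,
                                                        length(refSeq))))
    mutated[[cn]] <- Biostrings::DNAString(paste(pieces, collapse = ""))
  }
  # alleles for truths on chromosomes untouched above (none: loop covers all)
  new("PlantedGenome", chroms = genome@chroms, gene = gene,
      mutated = mutated, truths = truths,
      alleles = Biostrings::DNAStringSet(alleles))
}

#' @rdname PlantedGenome-class
#' @param x a `PlantedGenome`.
#' @export
insertionTruths <- function(x) x@truths

#' @rdname PlantedGenome-class
#' @export
insertionAlleles <- function(x) x@alleles

#' Draw a random insertion truth compatible with a genome
#'
#' Samples a target position away from chromosome ends, from the parental
#' gene, and from previously planted insertions; TSD length uniform over
#' `tsdLenRange`; strand uniform.
#'
#' @param genome [GenomeModel] or [PlantedGenome].
#' @param seed integer seed.
#' @param tsdLenRange candidate TSD lengths (default the 11-17 bp range
#'   observed for recent L1-mediated retrocopy insertions).
#' @param polyALen,trunc5,trunc3 passed to [InsertionTruth()].
#' @param minGap minimum distance from the gene and from other insertions.
#' @param endMargin keep-out zone at chromosome ends.
#' @return an [InsertionTruth].
#' @export
randomInsertionTruth <- function(genome, seed, tsdLenRange = 11:17,
                                 polyALen = 50L, trunc5 = 0L, trunc3 = 0L,
                                 minGap = 20000L, endMargin = 5000L) {
  set.seed(as.integer(seed))
  gene <- genome@gene
  gr <- geneRange(gene)
  existing <- if (is(genome, "PlantedGenome")) genome@truths else list()
  lens <- Biostrings::width(genome@chroms)
  names(lens) <- names(genome@chroms)
  for (attempt in seq_len(1000L)) {
    cn <- sample(names(lens), 1L)
    p <- sample.int(lens[[cn]] - 2L * endMargin, 1L) + endMargin
    bad <- cn == geneChrom(gene) &&
      p >= GenomicRanges::start(gr) - minGap &&
      p <= GenomicRanges::end(gr) + minGap
    for (tr in existing)
      if (tr@targetChrom == cn && abs(tr@targetPos - p) < minGap) bad <- TRUE
    if (!bad)
      return(InsertionTruth(cn, p,
                            tsdLen = sample(tsdLenRange, 1L),
                            strand = sample(c("+", "-"), 1L),
                            trunc5 = trunc5, trunc3 = trunc3,
                            polyALen = polyALen))
  }
  stop("could not place insertion; genome too crowded", call. = FALSE)
}

# --- read simulation ---------------------------------------------------------

#' Internal: per-chromosome insertion layout in mutated coordinates
#' @noRd
insertionLayout <- function(planted) {
  truths <- planted@truths
  if (!length(truths))
    return(data.frame(chrom = character(), T = integer(), Tp = integer(),
                      bodyLen = integer(), tsdLen = integer(), L = integer(),
                      shiftBefore = integer(), strand = character(),
                      trunc5 = integer(), M = integer(), p = integer()))
  mlen <- mrnaLength(planted@gene)
  df <- data.frame(
    chrom = vapply(truths, slot, "", "targetChrom"),
    T = vapply(truths, slot, 1L, "targetPos"),
    tsdLen = vapply(truths, slot, 1L, "tsdLen"),
    strand = vapply(truths, slot, "", "strand"),
    trunc5 = vapply(truths, slot, 1L, "trunc5"),
    trunc3 = vapply(truths, slot, 1L, "trunc3"),
    p = vapply(truths, slot, 1L, "polyALen"))
  df$M <- mlen - df$trunc5 - df$trunc3
  df$bodyLen <- df$M + df$p
  df$L <- df$bodyLen + df$tsdLen
  df <- df[order(df$chrom, df$T), , drop = FALSE]
  df$shiftBefore <- as.integer(stats::ave(df$L, df$chrom,
    FUN = function(x) cumsum(c(0, x[-length(x)]))))
  df$Tp <- as.integer(df$T + df$shiftBefore)
  df
}

#' Internal: map one insert-touching read back onto the reference
#'
#' Decomposes the read into flank / retrocopy-body / polyA pieces, anchors
#' it on the largest mappable piece (what a local aligner would do), and
#' soft-clips the rest.
#' @noRd
mapTouchingRead <- function(chrom, a, b, ins, gene) {
  pieces <- list()
  Tp <- ins$Tp; bodyLen <- ins$bodyLen
  M <- ins$M; p <- ins$p
  if (a <= Tp)
    pieces[[length(pieces) + 1L]] <- list(type = "ref", s = a, e = min(b, Tp),
      pos = a - ins$shiftBefore, shiftTotal = ins$shiftBefore)
  bs <- max(a, Tp + 1L); be <- min(b, Tp + bodyLen)
  if (bs <= be) {
    j1 <- bs - Tp; j2 <- be - Tp
    if (ins$strand == "+") {
      mj2 <- min(j2, M)
      if (j1 <= mj2) {
        lo <- ins$trunc5 + j1; hi <- ins$trunc5 + mj2
        pieces <- c(pieces, splitMrnaPiece(gene, lo, hi, flipped = FALSE,
          mutOf = function(mp) Tp + (mp - ins$trunc5)))
      }
    } else {
      mjs <- max(j1, p + 1L)
      if (mjs <= j2) {
        # body offset j maps to mRNA position trunc5 + (M - (j - p) + 1)
        hi <- ins$trunc5 + (M - (mjs - p) + 1L)
        lo <- ins$trunc5 + (M - (j2 - p) + 1L)
        pieces <- c(pieces, splitMrnaPiece(gene, lo, hi, flipped = TRUE,
          mutOf = function(mp) Tp + p + (ins$trunc5 + M - mp + 1L)))
      }
    }
  }
  if (b > Tp + bodyLen) {
    s <- max(a, Tp + bodyLen + 1L)
    pieces[[length(pieces) + 1L]] <- list(type = "ref", s = s, e = b,
      pos = s - ins$shiftBefore - bodyLen - ins$tsdLen,
      shiftTotal = ins$shiftBefore + ins$L)
  }
  if (!length(pieces))
    return(list(type = "unmapped"))
  lens <- vapply(pieces, function(z) z$e - z$s + 1L, 1L)
  best <- pieces[[which.max(lens)]]
  best$clipLeft <- best$s - a
  best$clipRight <- b - best$e
  best$matchLen <- best$e - best$s + 1L
  best
}

#' Internal: split an mRNA-mapped piece at exon boundaries; return mapped
#' sub-pieces with genomic positions.
#' @noRd
splitMrnaPiece <- function(gene, lo, hi, flipped, mutOf) {
  w <- IRanges::width(gene@exons)
  cum <- cumsum(w)
  out <- list()
  cur <- lo
  while (cur <= hi) {
    ex <- exonOfMrnaPos(gene, cur)
    if (gene@strand == "+") {
      exHiMrna <- cum[ex]
    } else {
      cumR <- cumsum(rev(w))
      exHiMrna <- cumR[length(w) - ex + 1L]
    }
    segHi <- min(hi, exHiMrna)
    g1 <- mrnaToGenomic(gene, cur); g2 <- mrnaToGenomic(gene, segHi)
    m1 <- mutOf(cur); m2 <- mutOf(segHi)
    flip <- xor(flipped, gene@strand == "-")
    out[[length(out) + 1L]] <- list(type = "exon",
      s = min(m1, m2), e = max(m1, m2),
      pos = min(g1, g2), exon = ex, flip = flip)
    cur <- segHi + 1L
  }
  out
}

#' Simulate paired-end alignments against the retrocopy-free reference
#'
#' Draws fragments from the mutated genome at the configured coverage and
#' emits one SAM record per mate, mapped in reference coordinates. Pairs
#' are labelled by construction as `concordant`, `junction_spanning`
#' (mates in different parental exons), `trans_mate` (one mate on the
#' parental gene, one at the insertion locus) or `other`.
#'
#' @param genome a [PlantedGenome] (or a plain [GenomeModel] for an
#'   insertion-free library).
#' @param config a [SimConfig].
#' @return a `RetroSimReads` list with elements `records` (SAM fields, one
#'   row per read), `truth` (per-pair class labels), `seqinfo` (reference
#'   chromosome lengths) and `config`.
#' @examples
#' g <- buildGenome(SimConfig(seed = 5), c(chrA = 30000, chrB = 20000),
#'                  geneStart = 10001)
#' p <- plantRetrocopy(g, InsertionTruth("chrB", 8000))
#' sim <- simulateAlignments(p, SimConfig(seed = 5, coverage = 4))
#' table(sim$truth$class)
#' @export
simulateAlignments <- function(genome, config = SimConfig()) {
  stopifnot(is(genome, "GenomeModel"), is(config, "SimConfig"))
  if (!is(genome, "PlantedGenome"))
    genome <- new("PlantedGenome", chroms = genome@chroms, gene = genome@gene,
                  mutated = genome@chroms, truths = list(),
                  alleles = Biostrings::DNAStringSet())
  gene <- genome@gene
  set.seed(config@seed)
  rl <- config@readLen
  layout <- insertionLayout(genome)
  refLens <- Biostrings::width(genome@chroms)
  names(refLens) <- names(genome@chroms)

  allRec <- list(); allTruth <- list(); pairOffset <- 0L
  for (cn in names(genome@mutated)) {
    mutSeq <- genome@mutated[[cn]]
    mutLen <- length(mutSeq)
    n <- round(config@coverage * mutLen / (2 * rl))
    if (n < 1L) next
    ins <- layout[layout$chrom == cn, , drop = FALSE]
    fl <- pmin(pmax(as.integer(round(stats::rnorm(n, config@insertMean,
                                                  config@insertSd))),
                    2L * rl), mutLen)
    st <- as.integer(floor(stats::runif(n, 1, mutLen - fl + 1 + 1 - 1e-9)))
    a1 <- st; b1 <- st + rl - 1L
    a2 <- st + fl - rl; b2 <- st + fl - 1L

    # which reads touch an insertion?
    touch <- function(a, b) {
      hit <- rep(0L, length(a))
      for (i in seq_len(nrow(ins)))
        hit[b > ins$Tp[i] & a <= ins$Tp[i] + ins$L[i]] <- i
      hit
    }
    t1 <- touch(a1, b1); t2 <- touch(a2, b2)
    bounds <- ins$Tp + ins$L
    cumL <- c(0L, cumsum(ins$L))
    shiftOf <- function(a) cumL[findInterval(a - 1L, bounds) + 1L]

    mk <- function(a, b, tch) {
      # per-read mapping: list-columns kept as plain vectors
      nr <- length(a)
      type <- rep("ref", nr); pos <- a - shiftOf(a)
      exonIdx <- rep(NA_integer_, nr); flip <- rep(FALSE, nr)
      clipL <- rep(0L, nr); clipR <- rep(0L, nr); mlen <- b - a + 1L
      shiftTot <- shiftOf(a)
      rname <- rep(cn, nr)
      for (j in which(tch > 0L)) {
        m <- mapTouchingRead(cn, a[j], b[j], ins[tch[j], ], gene)
        if (m$type == "unmapped") {
          type[j] <- "unmapped"; pos[j] <- 0L; mlen[j] <- 0L
        } else {
          type[j] <- m$type; pos[j] <- m$pos
          clipL[j] <- m$clipLeft; clipR[j] <- m$clipRight
          mlen[j] <- m$matchLen
          shiftTot[j] <- m$shiftTotal %||% NA_integer_
          if (m$type == "exon") {
            exonIdx[j] <- m$exon; flip[j] <- m$flip
            rname[j] <- geneChrom(gene)
          }
        }
      }
      list(type = type, pos = pos, exon = exonIdx, flip = flip,
           clipL = clipL, clipR = clipR, mlen = mlen, shift = shiftTot,
           rname = rname)
    }
    m1 <- mk(a1, b1, t1); m2 <- mk(a2, b2, t2)

    cls <- rep("concordant", n)
    un <- m1$type == "unmapped" | m2$type == "unmapped"
    bothRef <- m1$type == "ref" & m2$type == "ref"
    cls[bothRef & (m1$shift != m2$shift)] <- "other"
    bothEx <- m1$type == "exon" & m2$type == "exon"
    cls[bothEx & m1$exon != m2$exon] <- "junction_spanning"
    cls[xor(m1$type == "exon", m2$type == "exon") & !un] <- "trans_mate"
    cls[un] <- "other"

    pid <- sprintf("p%08d", pairOffset + seq_len(n))
    pairOffset <- pairOffset + n

    seqFor <- function(a, b, flipv) {
      s <- Biostrings::extractAt(mutSeq, IRanges::IRanges(a, pmax(a, b)))
      if (any(flipv)) s[flipv] <- Biostrings::reverseComplement(s[flipv])
      as.character(s)
    }
    s1 <- seqFor(a1, b1, m1$flip); s2 <- seqFor(a2, b2, m2$flip)
    if (config@errorRate > 0) {
      s1 <- addSubErrors(s1, config@errorRate)
      s2 <- addSubErrors(s2, config@errorRate)
    }

    rec <- buildSamRecords(pid, m1, m2, s1, s2, cls, rl)
    allRec[[cn]] <- rec
    allTruth[[cn]] <- data.frame(
      pairId = pid, class = cls,
      chrom1 = m1$rname, pos1 = m1$pos, strand1 = rec$strand1,
      chrom2 = m2$rname, pos2 = m2$pos, strand2 = rec$strand2,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(allRec, `[[`, "records"))
  rownames(records) <- NULL
  truth <- do.call(rbind, allTruth)
  rownames(truth) <- NULL
  structure(list(records = records, truth = truth,
                 seqinfo = refLens, config = config),
            class = "RetroSimReads")
}

#' Internal: uniform substitution errors
#' @noRd
addSubErrors <- function(seqs, rate) {
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nerr > 0L)
  for (j in idx) {
    ch <- strsplit(seqs[j], "", fixed = TRUE)[[1]]
    at <- sample.int(length(ch), nerr[j])
    for (k in at) ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1L)
    seqs[j] <- paste(ch, collapse = "")
  }
  seqs
}

#' Internal: assemble SAM fields for mate pairs
#' @noRd
buildSamRecords <- function(pid, m1, m2, s1, s2, cls, rl) {
  n <- length(pid)
  mkStrand <- function(m, mateMinus) {
    ifelse(m$type == "unmapped", "*",
           ifelse(xor(mateMinus, m$flip), "-", "+"))
  }
  st1 <- mkStrand(m1, FALSE); st2 <- mkStrand(m2, TRUE)
  cig <- function(m, flipv) {
    out <- character(length(m$pos))
    cl <- ifelse(flipv, m$clipR, m$clipL)
    cr <- ifelse(flipv, m$clipL, m$clipR)
    out <- paste0(ifelse(cl > 0L, paste0(cl, "S"), ""),
                  m$mlen, "M",
                  ifelse(cr > 0L, paste0(cr, "S"), ""))
    out[m$type == "unmapped"] <- "*"
    out
  }
  c1 <- cig(m1, m1$flip); c2 <- cig(m2, m2$flip)
  # flags
  f1 <- rep(0x1 + 0x40, n); f2 <- rep(0x1 + 0x80, n)
  proper <- cls == "concordant" & m1$type != "unmapped" &
    m2$type != "unmapped" & m1$rname == m2$rname
  f1[proper] <- f1[proper] + 0x2; f2[proper] <- f2[proper] + 0x2
  f1[st1 == "-"] <- f1[st1 == "-"] + 0x10
  f2[st2 == "-"] <- f2[st2 == "-"] + 0x10
  f1[st2 == "-"] <- f1[st2 == "-"] + 0x20
  f2[st1 == "-"] <- f2[st1 == "-"] + 0x20
  un1 <- m1$type == "unmapped"; un2 <- m2$type == "unmapped"
  f1[un1] <- f1[un1] + 0x4; f2[un2] <- f2[un2] + 0x4
  f1[un2] <- f1[un2] + 0x8; f2[un1] <- f2[un1] + 0x8
  # placement of unmapped mates at their partner's locus
  r1 <- m1$rname; p1 <- m1$pos; r2 <- m2$rname; p2 <- m2$pos
  r1[un1] <- r2[un1]; p1[un1] <- p2[un1]
  r2[un2] <- r1[un2]; p2[un2] <- p1[un2]
  e1 <- p1 + m1$mlen - 1L; e2 <- p2 + m2$mlen - 1L
  same <- r1 == r2 & !un1 & !un2
  tl <- integer(n)
  lo <- pmin(p1, p2); hi <- pmax(e1, e2)
  tl1 <- ifelse(same, ifelse(p1 <= p2, hi - lo + 1L, -(hi - lo + 1L)), 0L)
  mapq <- function(un) ifelse(un, 0L, 60L)
  records <- data.frame(
    qname = rep(pid, 2L),
    flag = c(f1, f2),
    rname = c(r1, r2),
    pos = c(p1, p2),
    mapq = c(mapq(un1), mapq(un2)),
    cigar = c(c1, c2),
    rnext = rep("=", 2L * n),
    pnext = c(p2, p1),
    tlen = c(tl1, -tl1),
    seq = c(s1, s2),
    qual = strrep("I", nchar(c(s1, s2))),
    stringsAsFactors = FALSE)
  records$rnext <- c(ifelse(r2 == r1, "=", r2), ifelse(r1 == r2, "=", r1))
  # interleave mates
  ord <- as.vector(rbind(seq_len(n), n + seq_len(n)))
  records <- records[ord, , drop = FALSE]
  list(records = records, strand1 = st1, strand2 = st2)
}

#' Write simulated reads as SAM
#'
#' Emits a valid SAM file with `@SQ` headers for the reference chromosomes.
#' Byte-identical for identical [SimConfig] seeds.
#'
#' @param sim a `RetroSimReads` object from [simulateAlignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(sim, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$seqinfo), sim$seqinfo),
           "@PG\tID:retroseek\tPN:retroseek")
  r <- sim$records
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                  r$rnext, r$pnext, r$tlen, r$seq, r$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write genome sequences as FASTA
#'
#' @param genome a [GenomeModel] or [PlantedGenome].
#' @param path output path.
#' @param which `"reference"` or `"mutated"` chromosomes.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path,
                             which = c("reference", "mutated")) {
  which <- match.arg(which)
  seqs <- if (which == "mutated") {
    stopifnot(is(genome, "PlantedGenome"))
    genome@mutated
  } else genome@chroms
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write planted-insertion truth as BED
#'
#' One line per insertion covering the TSD interval
#' `[targetPos - tsdLen + 1, targetPos]` (converted to BED's 0-based
#' half-open convention), name `site1..siteN`, strand column carrying the
#' retrocopy orientation.
#'
#' @param planted a [PlantedGenome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(planted, path) {
  stopifnot(is(planted, "PlantedGenome"))
  tr <- planted@truths
  lines <- vapply(seq_along(tr), function(i) {
    t <- tr[[i]]
    s1 <- t@targetPos - max(t@tsdLen, 1L) + 1L
    sprintf("%s\t%d\t%d\tsite%d\t%d\t%s",
            t@targetChrom, oneToZeroStart(s1), t@targetPos, i,
            t@tsdLen, t@strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-pair truth labels as TSV
#'
#' @param sim a `RetroSimReads` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthPairs <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
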