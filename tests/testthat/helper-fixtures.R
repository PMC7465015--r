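# Shared fixtures: all built in code at test time.

# Small deterministic gene model (3 exons, 400 bp mRNA) for unit tests.
toyGene <- function(seed = 1, chrom = "chrT", strand = "+") {
  set.seed(seed)
  mrna <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  # exons 150/100/150 with introns 1000/500 starting at 1001
  GeneModel(chrom, strand,
            exonStarts = c(1001L, 2151L, 2751L),
            exonEnds = c(1150L, 2250L, 2900L),
            utr5Len = 80L, orfLen = 120L, mrna = mrna)
}

# Random DNA string.
randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Published insertion-site rows with reconstructed junction contexts.
table1Contexts <- function() {
  s <- fgf4InsertionSites()
  s$ctx5 <- paste0(s$flank5, s$tsd)
  s$ctx3 <- paste0(s$tsd, s$flank3)
  s
}

# Independent brute-force TSD oracle: enumerate every candidate length and
# compare the suffix/prefix character pairs directly; returns the longest
# exact duplication length (0 if none in bounds).
bruteTsdLen <- function(ctx5, ctx3, minLen = 6L, maxLen = 30L) {
  a <- strsplit(ctx5, "")[[1]]
  b <- strsplit(ctx3, "")[[1]]
  best <- 0L
  for (L in seq(minLen, min(maxLen, length(a), length(b)))) {
    suf <- a[seq(length(a) - L + 1L, length(a))]
    pre <- b[seq_len(L)]
    if (all(suf == pre)) best <- L
  }
  best
}

# Write a minimal VCFv4.2 with the given site table.
writeMiniVcf <- function(df, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(df))
    sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t.",
            df$chrom, df$pos, df$ref, df$alt) else character(0)
  writeLines(c(hdr, body), path)
  path
}

# Gene model on "chr18" whose 3' UTR covers the canonical canid FGF4
# variant positions (exon3 spans 48,414,581-48,417,200). The ORF region
# is a genuine reading frame (ATG...stop, no internal stops).
fgf4LikeGene <- function(seed = 9) {
  exL <- c(476L, 104L, 2620L); inL <- c(1300L, 700L)
  geneStart <- 48412001L
  st <- geneStart + cumsum(c(0L, exL[-3] + inL))
  en <- st + exL - 1L
  set.seed(seed)
  mrna <- randomDna(3200L)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  orfSeq <- paste0("ATG", paste(sample(sense, 621L / 3L - 2L,
                                       replace = TRUE), collapse = ""),
                   "TAA")
  mrna <- paste0(substr(mrna, 1, 480), orfSeq, substr(mrna, 1102, 3200))
  GeneModel("chr18", "+", st, en, 480L, 621L, mrna = mrna)
}

# One simulate+scan cycle against a prebuilt genome.
simulateAndScan <- function(planted, simSeed, coverage = 20, ...) {
  sim <- simulateAlignments(planted, SimConfig(seed = simSeed,
                                               coverage = coverage))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeSam(sim, sam)
  scanSample(sam, planted@gene, ...)
}

# Does a call set contain a CONFIDENT call whose interval covers pos?
confidentAt <- function(calls, chrom, pos) {
  if (length(calls) == 0L) return(FALSE)
  any(calls$status == "CONFIDENT" &
        as.character(GenomicRanges::seqnames(calls)) == chrom &
        GenomicRanges::start(calls) <= pos &
        GenomicRanges::end(calls) >= pos)
}
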