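# Insertion-site characterization: TSD finder, G/C window, motif scan,
# conserved-element counting, truncation classification.

test_that("G/C window reproduces the published values for all seven sites", {
  s <- table1Contexts()
  gc <- mapply(function(f5, t, f3) gcWindow(paste0(f5, t, f3)),
               s$flank5, s$tsd, s$flank3)
  expect_equal(unname(gc), s$gc)
  # 6 of the 7 sites fall below the genome-average G/C of 41.3%
  expect_equal(sum(gc < 41.3), 6L)
})

test_that("G/C arithmetic rounds half-up and rejects ambiguity codes", {
  expect_equal(gcWindow("ATAT"), 0.0)
  expect_equal(gcWindow("GCGC"), 100.0)
  # 12/33 = 36.3636... rounds to 36.4
  expect_equal(gcWindow(paste0(strrep("G", 12), strrep("A", 21))), 36.4)
  # 1/8 = 12.5: exact half at the first decimal stays (half-up no-op here);
  # 7/40 = 17.5 from a .5-exact ratio
  expect_equal(gcWindow(paste0(strrep("C", 7), strrep("T", 33))), 17.5)
  expect_error(gcWindow("ACGTN"), "non-ACGT")
  expect_error(gcWindow(""), "non-empty")
})

test_that("TSD finder recovers the published range across the seven sites", {
  s <- table1Contexts()
  res <- mapply(function(c5, c3) findTsd(c5, c3)$tsdLen, s$ctx5, s$ctx3)
  expect_equal(unname(res), nchar(s$tsd))
  expect_equal(min(res), 11L)
  expect_equal(max(res), 17L)
  # the computed median of the printed rows is 14
  expect_equal(unname(stats::median(res)), 14)
})

test_that("TSD finder agrees with the brute-force oracle on random junctions", {
  set.seed(202)
  for (i in 1:100) {
    tsdLen <- sample(6:25, 1)
    tsd <- randomDna(tsdLen)
    ctx5 <- paste0(randomDna(15), tsd)
    ctx3 <- paste0(tsd, randomDna(15))
    got <- findTsd(ctx5, ctx3)
    oracle <- bruteTsdLen(ctx5, ctx3)
    expect_equal(got$tsdLen, oracle)
    # the detected string is genuinely duplicated at both junctions
    expect_identical(substr(ctx5, nchar(ctx5) - got$tsdLen + 1, nchar(ctx5)),
                     got$tsdSeq)
    expect_identical(substr(ctx3, 1, got$tsdLen), got$tsdSeq)
  }
})

test_that("TSD finder edge cases: no duplication, mismatch tolerance, bounds", {
  # contexts engineered to share no >= 6 bp suffix/prefix duplication
  expect_null(findTsd("ACACACACACACAC", "GTGTGTGTGTGTGT"))
  expect_error(findTsd("ACGT", "ACGTA"), "at least minLen")
  expect_error(findTsd("ACGTNACGTA", "ACGTAACGTA"), "non-ACGT")
  # one internal mismatch: invisible at maxMismatch 0, found at 1
  tsd <- "AAGTCAGACAGAG"
  tsdMut <- sub("CAGACA", "CAGCCA", tsd)
  c5 <- paste0("ACCATGAAAT", tsd)
  c3 <- paste0(tsdMut, "AAAGACAAGT")
  exact <- findTsd(c5, c3)
  expect_true(is.null(exact) || exact$tsdLen < nchar(tsd))
  fuzzy <- findTsd(c5, c3, maxMismatch = 1)
  expect_equal(fuzzy$tsdLen, nchar(tsd))
  expect_equal(fuzzy$mismatches, 1L)
})

test_that("motif scan finds overlapping forward hits and optional revcomp", {
  expect_equal(scanMotif("TTAAAATTAAAA"), c(1L, 7L))
  expect_equal(scanMotif("GGGGGG"), integer(0))
  # overlapping occurrences are all reported
  expect_equal(scanMotif("TTTTAAAAAA", motif = "TTAA"), 3L)
  both <- scanMotif("GGGTAAGGGG", motif = "TTAC", bothStrands = TRUE)
  expect_equal(both$forward, integer(0))
  expect_equal(both$reverse, 3L)  # GTAA = revcomp(TTAC) at offset 3
  expect_error(scanMotif("ACGT", motif = ""), "non-empty")
})

test_that("the L1 motif is found only in the one published window", {
  s <- table1Contexts()
  hits <- mapply(function(f5, t, f3) length(scanMotif(paste0(f5, t, f3))),
                 s$flank5, s$tsd, s$flank3)
  expect_equal(sum(hits >= 1), 1L)
  expect_equal(s$name[hits >= 1], "FGF4L5")
})

test_that("conserved-element counting uses >=1 shared base in a 2.5 kb radius", {
  site <- list(chrom = "chr1", start = 100000L, end = 100032L)
  mid <- (100000L + 100032L) %/% 2L
  inside <- mid + c(-2400L, -1000L, -100L, 50L, 1200L, 2400L)
  outside <- mid + c(-4000L, 3500L)
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tE%d", c(inside, outside) - 1L,
                     c(inside, outside) + 49L, seq_along(c(inside, outside))),
             bed)
  expect_equal(countEcr(site, bed), 6L)
  # empty annotation
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(countEcr(site, empty), 0L)
  # an element exactly abutting the window edge shares no base: excluded;
  # brute-force closed-interval check confirms
  lo <- mid - 2500L; hi <- mid + 2500L
  abut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(hi + 1L, hi + 50L))
  just <- GenomicRanges::GRanges("chr1", IRanges::IRanges(hi, hi + 50L))
  expect_equal(countEcr(site, abut), 0L)
  expect_equal(countEcr(site, just), 1L)
  expect_false(max(lo, hi + 1L) <= min(hi, hi + 50L))  # brute: empty overlap
  expect_true(max(lo, hi) <= min(hi, hi + 50L))
  unlink(c(bed, empty))
})

test_that("malformed BED lines are reported with their line number", {
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\tnothere\t300"), bad)
  expect_error(readBedIntervals(bad), "line 2")
  unlink(bad)
})

test_that("truncation classification measures missing UTR sequence", {
  gene <- fgf4LikeGene()
  mrna <- as.character(mrnaSeq(gene))
  full <- classifyTruncation(mrna, gene)
  expect_equal(full@trunc5, 0L)
  expect_equal(full@trunc3, 0L)
  expect_true(full@orfIntact)

  # 112 bp lopped off the 5' UTR
  t112 <- classifyTruncation(substr(mrna, 113L, nchar(mrna)), gene)
  expect_equal(t112@trunc5, 112L)
  expect_equal(t112@trunc3, 0L)
  expect_true(t112@orfIntact)

  # 3' truncations of 530 and 83 bp stay inside the long 3' UTR
  for (d in c(530L, 83L)) {
    r <- classifyTruncation(substr(mrna, 1L, nchar(mrna) - d), gene)
    expect_equal(r@trunc3, d)
    expect_true(r@orfIntact)
  }

  # polyA tail is stripped, not reported as extra sequence
  tailed <- classifyTruncation(paste0(mrna, strrep("A", 40)), gene)
  expect_equal(tailed@trunc3, 0L)

  # a 3'-UTR-only fragment has no ORF
  frag <- classifyTruncation(substr(mrna, 1680L, nchar(mrna)), gene)
  expect_false(frag@orfIntact)
  expect_equal(frag@trunc5, 1679L)

  # an unrelated sequence is rejected
  expect_error(classifyTruncation(randomDna(1000, seed = 5), gene),
               "not a retrocopy")
})

test_that("ORF intactness is sensitive to premature stops and indels", {
  gene <- fgf4LikeGene()
  mrna <- strsplit(as.character(mrnaSeq(gene)), "")[[1]]
  # force a premature stop early in the ORF: find a codon we can make TAA
  orfStart <- IRanges::start(retroseek::orf(gene))
  codon1 <- orfStart + 3L  # second codon
  mut <- mrna
  mut[codon1:(codon1 + 2L)] <- c("T", "A", "A")
  r <- classifyTruncation(paste(mut, collapse = ""), gene)
  expect_false(r@orfIntact)
  # single-base deletion inside the ORF shifts the frame
  del <- mrna[-(orfStart + 10L)]
  r2 <- classifyTruncation(paste(del, collapse = ""), gene)
  expect_false(r2@orfIntact)
})

test_that("characterizeSite assembles the full report", {
  s <- table1Contexts()
  i <- which(s$name == "FGF4L5")
  rep5 <- characterizeSite("FGF4L5", s$ctx5[i], s$ctx3[i], strand = "+")
  expect_s4_class(rep5, "SiteReport")
  expect_equal(rep5@tsdLen, 16L)
  expect_equal(rep5@gcPercent, 36.1)
  expect_length(rep5@motifHits, 1L)
  expect_identical(siteWindow(rep5), paste0(s$flank5[i], s$tsd[i],
                                            s$flank3[i]))
  # repeat context from an annotation overlap
  reps <- GenomicRanges::GRanges("chr13", IRanges::IRanges(28019000, 28021000),
                                 name = "LINE")
  rep5b <- characterizeSite("FGF4L5", s$ctx5[i], s$ctx3[i], strand = "+",
                            insertionInterval = list(chrom = "chr13",
                                                     start = s$start[i],
                                                     end = s$end[i]),
                            repeats = reps)
  expect_equal(rep5b@repeatContext, "LINE")
})
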