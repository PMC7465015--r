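# Discordant-pair classification, trans-mate clustering and insertion
# calling.

# Hand-built pair table around toyGene(): exons at 1001-1150, 2151-2250,
# 2751-2900 on chrT.
mkPair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                   readLen = 100L, id = "p1") {
  data.frame(pairId = id,
             chrom1 = chrom1, pos1 = pos1, end1 = pos1 + readLen - 1L,
             strand1 = strand1, cigar1 = paste0(readLen, "M"),
             seq1 = strrep("A", readLen), clipLeft1 = 0L, clipRight1 = 0L,
             chrom2 = chrom2, pos2 = pos2, end2 = pos2 + readLen - 1L,
             strand2 = strand2, cigar2 = paste0(readLen, "M"),
             seq2 = strrep("A", readLen), clipLeft2 = 0L, clipRight2 = 0L,
             stringsAsFactors = FALSE)
}

test_that("pair classification implements the two discordance signals", {
  gene <- toyGene()
  pairs <- rbind(
    mkPair("chrT", 1020, "+", "chrT", 2800, "-", id = "junction"),
    mkPair("chrT", 2760, "+", "chrT", 2790, "-", id = "concordant"),
    mkPair("chrT", 1020, "+", "chrX", 50000, "-", id = "trans"),
    mkPair("chrT", 1020, "+", "chrT", 1500, "-", id = "nearNoise"),
    mkPair("chrT", 1020, "+", NA_character_, NA, NA_character_,
           id = "unmapped"))
  pairs$pos2[5] <- NA_integer_; pairs$end2[5] <- NA_integer_
  cls <- classifyPairs(pairs, gene, insertMean = 400, insertSd = 50)
  got <- setNames(cls$class, cls$pairId)
  # exon1 -> exon3 with ~1.9 kb span: intron-scale inflation
  expect_equal(unname(got["junction"]), "JUNCTION_SPANNING")
  expect_equal(unname(got["concordant"]), "CONCORDANT")
  # one mate on the gene, one on another chromosome: insertion-site signal
  expect_equal(unname(got["trans"]), "TRANS_MATE")
  # a mate within the exclusion radius is local noise, not trans evidence
  expect_false(got["nearNoise"] == "TRANS_MATE")
  expect_equal(unname(got["unmapped"]), "OTHER")
  # exhaustive and mutually exclusive
  expect_true(all(cls$class %in%
    c("CONCORDANT", "JUNCTION_SPANNING", "TRANS_MATE", "OTHER")))
  expect_equal(nrow(cls), nrow(pairs))
})

test_that("junction calls require intron-scale span, not just different exons", {
  gene <- toyGene()
  # exon2 -> exon3 mates, but template span ~400: within library noise
  p <- mkPair("chrT", 2200, "+", "chrT", 2800, "-")
  cls <- classifyPairs(p, gene, insertMean = 700, insertSd = 50)
  expect_false(cls$class == "JUNCTION_SPANNING")
  # same mates, tight library: now discordant
  cls2 <- classifyPairs(p, gene, insertMean = 300, insertSd = 50)
  expect_equal(cls2$class, "JUNCTION_SPANNING")
})

test_that("trans-mate clustering is single-linkage with a gap window", {
  gene <- toyGene()
  mk <- function(pos, id) mkPair("chrT", 1020, "+", "chrZ", pos, "-",
                                 readLen = 1L, id = id)
  pairs <- rbind(mk(10000, "a"), mk(10150, "b"), mk(10400, "c"))
  pairs$class <- "TRANS_MATE"
  cl <- clusterTransMates(pairs, gene, clusterWindow = 300)
  expect_equal(nrow(cl), 1L)  # chain linkage joins all three
  expect_equal(cl$n, 3L)

  pairs2 <- rbind(mk(10000, "a"), mk(12000, "b"))
  pairs2$class <- "TRANS_MATE"
  cl2 <- clusterTransMates(pairs2, gene, clusterWindow = 300)
  expect_equal(nrow(cl2), 2L)

  empty <- pairs2[0, ]
  expect_equal(nrow(clusterTransMates(empty, gene)), 0L)
})

test_that("calling applies the both-signals rule", {
  gene <- toyGene()
  mk <- function(pos, id, strand = "-") mkPair("chrT", 1020, "+", "chrZ",
                                               pos, strand, id = id)
  # 5 trans pairs, 0 junction pairs: localized but not CONFIDENT
  rawTrans <- do.call(rbind, lapply(1:5, function(i)
    mk(10000 + 20 * i, paste0("t", i))))
  pairs <- classifyPairs(rawTrans, gene)
  calls <- callInsertions(pairs, gene)
  expect_equal(length(calls), 1L)
  expect_equal(calls$status, "CANDIDATE")

  # two trans pairs only: reported as a followup candidate
  pairs2 <- classifyPairs(do.call(rbind, lapply(1:2, function(i)
    mk(10000 + 20 * i, paste0("t", i)))), gene)
  calls2 <- callInsertions(pairs2, gene)
  expect_equal(calls2$status, "CANDIDATE")

  # one trans pair: below the reporting floor
  calls1 <- callInsertions(classifyPairs(mk(10000, "t1"), gene), gene)
  expect_equal(length(calls1), 0L)

  # junction support present: CONFIDENT; orientation from strand consensus
  junc <- do.call(rbind, lapply(1:3, function(i)
    mkPair("chrT", 1020, "+", "chrT", 2800, "-", id = paste0("j", i))))
  pairs3 <- classifyPairs(rbind(rawTrans, junc), gene)
  calls3 <- callInsertions(pairs3, gene)
  expect_equal(calls3$status[1], "CONFIDENT")
  expect_equal(calls3$orientation[1], "-")  # all outside mates reverse

  # mixed outside-mate strands below 80% agreement: unknown orientation
  mixed <- rbind(mk(10000, "m1", "+"), mk(10020, "m2", "-"),
                 mk(10040, "m3", "+"), mk(10060, "m4", "-"))
  calls4 <- callInsertions(classifyPairs(rbind(mixed, junc), gene), gene)
  expect_equal(calls4$orientation[1], "unknown")

  # overlap with an annotated reference retrocopy fragment demotes the call
  frag <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(9900, 10200))
  calls5 <- callInsertions(pairs3, gene, fragments = frag)
  expect_equal(calls5$status[1], "FRAGMENT")
})

test_that("raising minTrans never increases CONFIDENT calls", {
  g <- buildGenome(SimConfig(seed = 71),
                   chromLengths = c(chrA = 60000L, chrB = 40000L),
                   geneStart = 20001L)
  p <- plantRetrocopy(g, InsertionTruth("chrB", 20000L, tsdLen = 15L))
  sim <- simulateAlignments(p, SimConfig(seed = 9, coverage = 15))
  sam <- tempfile(fileext = ".sam")
  writeSam(sim, sam)
  pairs <- classifyPairs(readPairs(sam), g@gene)
  nConf <- vapply(c(1L, 3L, 10L, 50L, 1000L), function(mt) {
    calls <- callInsertions(pairs, g@gene, minTrans = mt,
                            minTransCandidate = 1L)
    sum(calls$status == "CONFIDENT")
  }, 1L)
  expect_true(all(diff(nConf) <= 0))
  unlink(sam)
})

test_that("a planted insertion is recovered and a clean genome yields no calls", {
  g <- buildGenome(SimConfig(seed = 81),
                   chromLengths = c(chrA = 80000L, chrB = 60000L),
                   geneStart = 30001L)
  tr <- InsertionTruth("chrB", 30000L, tsdLen = 12L)
  p <- plantRetrocopy(g, tr)
  res <- simulateAndScan(p, simSeed = 10)
  expect_true(confidentAt(res$calls, "chrB", 30000L))

  # determinism: the same input yields identical calls
  res2 <- simulateAndScan(p, simSeed = 10)
  expect_identical(as.data.frame(res$calls), as.data.frame(res2$calls))

  # insertion-free genome: zero calls
  res0 <- simulateAndScan(g, simSeed = 10)
  expect_equal(length(res0$calls), 0L)

  # two planted insertions give two clusters at the truth loci
  p2 <- plantRetrocopy(p, InsertionTruth("chrA", 70000L, tsdLen = 16L))
  res3 <- simulateAndScan(p2, simSeed = 11)
  expect_equal(length(res3$calls), 2L)
  expect_true(confidentAt(res3$calls, "chrB", 30000L))
  expect_true(confidentAt(res3$calls, "chrA", 70000L))
})

test_that("cohort screening flags carriers and survives bad files", {
  g <- buildGenome(SimConfig(seed = 91),
                   chromLengths = c(chrA = 60000L, chrB = 40000L),
                   geneStart = 20001L)
  p <- plantRetrocopy(g, InsertionTruth("chrB", 20000L))
  sams <- character(3)
  for (i in 1:3) {
    src <- if (i <= 2) p else g   # carrier, carrier, non-carrier
    sim <- simulateAlignments(src, SimConfig(seed = 100 + i, coverage = 15))
    sams[i] <- tempfile(fileext = ".sam")
    writeSam(sim, sams[i])
  }
  names(sams) <- c("s1", "s2", "s3")
  tab <- screenCohort(sams, g@gene)
  carriers <- unique(tab$sample[!is.na(tab$callStatus) &
                                  tab$callStatus == "CONFIDENT"])
  expect_setequal(carriers, c("s1", "s2"))
  expect_true("s3" %in% tab$sample)  # zero-call sample still listed
  expect_true(all(is.na(tab$callStatus[tab$sample == "s3"])))

  # unreadable file: marked failed, batch continues
  bad <- c(sams, s4 = tempfile(fileext = ".sam"))
  writeLines("not a sam file", bad[["s4"]])
  suppressMessages(tab2 <- screenCohort(bad, g@gene))
  expect_equal(tab2$status[tab2$sample == "s4"], "failed")
  expect_setequal(unique(tab2$sample), c("s1", "s2", "s3", "s4"))

  # header-only SAM: zero calls, sample listed as ok
  hdr <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrT\tLN:10000"), hdr)
  tab3 <- screenCohort(c(s5 = hdr), g@gene)
  expect_equal(tab3$status, "ok")
  expect_true(is.na(tab3$callStatus))
  unlink(c(sams, bad[["s4"]], hdr))
})
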