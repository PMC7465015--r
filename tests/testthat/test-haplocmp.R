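# Retrocopy-vs-parental variant calling and haplotype classification.

test_that("an unchanged retrocopy yields an empty variant list", {
  gene <- fgf4LikeGene()
  vars <- alignAndCall(as.character(mrnaSeq(gene)), gene)
  expect_equal(nrow(vars), 0L)
})

test_that("planted variants are recovered with position, alleles and region", {
  gene <- fgf4LikeGene()
  mrna <- strsplit(as.character(mrnaSeq(gene)), "")[[1]]
  mlen <- length(mrna)
  u3start <- IRanges::start(utr3(gene))
  set.seed(303)
  for (rep in 1:25) {
    retro <- mrna
    # plant 1-4 SNVs away from each other and from the sequence ends
    k <- sample(1:4, 1)
    at <- sort(sample(seq(50L, mlen - 50L), k))
    while (any(diff(at) < 10L)) at <- sort(sample(seq(50L, mlen - 50L), k))
    alt <- vapply(at, function(i)
      sample(setdiff(c("A", "C", "G", "T"), retro[i]), 1), "")
    ref <- retro[at]
    retro[at] <- alt
    vars <- alignAndCall(paste(retro, collapse = ""), gene)
    snv <- vars[vars$kind == "SNV", ]
    expect_equal(snv$mrnaPos, at)
    expect_equal(snv$ref, ref)
    expect_equal(snv$alt, alt)
    expect_equal(snv$region, mrnaRegion(gene, at))
    expect_equal(snv$genomicPos, mrnaToGenomic(gene, at))
    # idempotence: a second call on the same sequence is identical
    expect_identical(vars, alignAndCall(paste(retro, collapse = ""), gene))
  }
})

test_that("planted indels are recovered and left-normalized", {
  gene <- fgf4LikeGene()
  mrna <- strsplit(as.character(mrnaSeq(gene)), "")[[1]]
  # deletion in a context with no homopolymer ambiguity: delete one base
  # and check a del variant lands at (or left of) the planted spot
  set.seed(304)
  for (rep in 1:10) {
    at <- sample(seq(600L, 3000L), 1)
    retro <- paste(mrna[-at], collapse = "")
    vars <- alignAndCall(retro, gene)
    expect_equal(nrow(vars), 1L)
    expect_equal(vars$kind, "del")
    expect_lte(vars$mrnaPos, at)  # left-normalization can shift left only
    expect_equal(nchar(vars$ref), 2L)
    expect_equal(nchar(vars$alt), 1L)
    # insertion of one base
    ins <- sample(c("A", "C", "G", "T"), 1)
    retroIns <- paste(c(mrna[1:at], ins, mrna[(at + 1L):length(mrna)]),
                      collapse = "")
    vi <- alignAndCall(retroIns, gene)
    expect_equal(nrow(vi), 1L)
    expect_equal(vi$kind, "ins")
    expect_equal(nchar(vi$ref), 1L)
    expect_equal(nchar(vi$alt), 2L)
  }
  # canonical left-shift: deleting one A from an A-run reports the anchor
  # before the run
  runStart <- 700L
  mrnaRun <- mrna
  mrnaRun[runStart:(runStart + 3L)] <- "A"
  geneRun <- GeneModel(geneChrom(gene), geneStrand(gene),
                       IRanges::start(exons(gene)), IRanges::end(exons(gene)),
                       IRanges::width(utr5(gene)), IRanges::width(orf(gene)),
                       paste(mrnaRun, collapse = ""))
  retro <- paste(mrnaRun[-(runStart + 2L)], collapse = "")  # delete mid-run
  v <- alignAndCall(retro, geneRun)
  expect_equal(v$kind, "del")
  expect_lte(v$mrnaPos, runStart)
})

test_that("variant classification against the population table partitions", {
  gene <- fgf4LikeGene()
  mrna <- strsplit(as.character(mrnaSeq(gene)), "")[[1]]
  pos <- c(48415400L, 48415405L, 48415585L, 48415608L, 48415661L, 48416537L)
  mp <- genomicToMrna(gene, pos)
  set.seed(305)
  alt <- vapply(mp, function(i)
    sample(setdiff(c("A", "C", "G", "T"), mrna[i]), 1), "")
  ref <- mrna[mp]
  retro <- mrna
  retro[mp] <- alt
  # plus a single-base deletion (the post-insertion candidate)
  delMp <- genomicToMrna(gene, 48415685L)
  retroSeq <- paste(retro[-delMp], collapse = "")
  vars <- alignAndCall(retroSeq, gene)
  expect_equal(nrow(vars), 7L)

  # population VCF carrying every variant: everything is haplotype-derived
  popAll <- data.frame(chrom = vars$chrom, pos = vars$genomicPos,
                       ref = vars$ref, alt = vars$alt)
  vcfAll <- writeMiniVcf(popAll, tempfile(fileext = ".vcf"),
                         contigs = c(chr18 = 48500000L))
  clAll <- classifyVariants(vars, vcfAll)
  expect_equal(sum(clAll$classification == "HAPLOTYPE_SHARED"), 7L)
  expect_equal(sum(clAll$classification == "RETROCOPY_SPECIFIC"), 0L)

  # drop the indel from the table: exactly that variant flips
  popNoDel <- popAll[vars$kind != "del", ]
  vcfNoDel <- writeMiniVcf(popNoDel, tempfile(fileext = ".vcf"),
                           contigs = c(chr18 = 48500000L))
  clNoDel <- classifyVariants(vars, vcfNoDel)
  flipped <- clNoDel[clNoDel$classification == "RETROCOPY_SPECIFIC", ]
  expect_equal(nrow(flipped), 1L)
  expect_equal(flipped$kind, "del")

  # same position, different allele: not shared (allele identity required)
  popWrongAlt <- popAll
  popWrongAlt$alt[1] <- setdiff(c("A", "C", "G", "T"),
                                c(popAll$ref[1], popAll$alt[1]))[1]
  clWrong <- classifyVariants(vars, popWrongAlt)
  expect_equal(clWrong$classification[1], "RETROCOPY_SPECIFIC")

  # empty table: everything retrocopy-specific
  vcfEmpty <- writeMiniVcf(popAll[0, ], tempfile(fileext = ".vcf"),
                           contigs = c(chr18 = 48500000L))
  clEmpty <- classifyVariants(vars, vcfEmpty)
  expect_true(all(clEmpty$classification == "RETROCOPY_SPECIFIC"))

  # partition: every variant gets exactly one class and counts sum
  s <- summarizeVariants(clAll)
  expect_equal(s$nHaplotypeShared + s$nRetrocopySpecific, s$nVariants)
  unlink(c(vcfAll, vcfNoDel, vcfEmpty))
})

test_that("multiallelic VCF records are split before lookup", {
  df <- data.frame(chrom = "chr18", pos = 100L, ref = "G", alt = "A,C")
  vcf <- writeMiniVcf(df, tempfile(fileext = ".vcf"),
                      contigs = c(chr18 = 1000L))
  pop <- readPopulationVcf(vcf)
  expect_equal(nrow(pop), 2L)
  expect_setequal(pop$alt, c("A", "C"))
  expect_true(all(pop$pos == 100L))
  unlink(vcf)
})

test_that("haplotype matching finds the source haplotype", {
  gene <- fgf4LikeGene()
  mrna <- strsplit(as.character(mrnaSeq(gene)), "")[[1]]
  set.seed(306)
  sites <- sort(sample(seq(1700L, 3100L), 6))
  gpos <- mrnaToGenomic(gene, sites)
  refAl <- mrna[sites]
  altAl <- vapply(sites, function(i)
    sample(setdiff(c("A", "C", "G", "T"), mrna[i]), 1), "")
  # four phased haplotypes: H1 = reference; H2..H4 carry different subsets
  carrier <- list(H1 = rep(FALSE, 6), H2 = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                  H3 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                  H4 = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  hap <- do.call(rbind, lapply(names(carrier), function(h)
    data.frame(haplotype = h, pos = gpos,
               allele = ifelse(carrier[[h]], altAl, refAl))))
  # retrocopy copied from H2
  retro <- mrna
  retro[sites[carrier$H2]] <- altAl[carrier$H2]
  vars <- alignAndCall(paste(retro, collapse = ""), gene)
  m <- haplotypeMatch(vars, hap, refAlleles = setNames(refAl, gpos))
  expect_equal(m$best, "H2")
  expect_equal(m$mismatches, 0L)

  # one post-insertion mutation on top of H2
  extra <- which(!carrier$H2)[1]
  retro2 <- retro
  retro2[sites[extra]] <- altAl[extra]
  vars2 <- alignAndCall(paste(retro2, collapse = ""), gene)
  m2 <- haplotypeMatch(vars2, hap, refAlleles = setNames(refAl, gpos))
  expect_equal(m2$best, "H2")
  expect_equal(m2$mismatches, 1L)

  # a single shared haplotype matches trivially
  m3 <- haplotypeMatch(vars, hap[hap$haplotype == "H2", ],
                       refAlleles = setNames(refAl, gpos))
  expect_equal(m3$best, "H2")

  # no haplotype covers the positions: UNKNOWN with a warning
  hapPartial <- hap[hap$pos != gpos[1], ]
  expect_warning(m4 <- haplotypeMatch(vars, hapPartial,
                                      refAlleles = setNames(refAl, gpos)),
                 "covers")
  expect_equal(m4$classification, "UNKNOWN")
})

test_that("dissimilar or short sequences are rejected", {
  gene <- fgf4LikeGene()
  expect_error(alignAndCall(randomDna(150, seed = 7), gene), ">= 200")
  expect_error(alignAndCall(randomDna(2000, seed = 8), gene),
               "not a retrocopy")
})
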