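# In-silico support for PCR assays and population genotyping: amplicon
# size prediction for exon-to-exon assays, cohort allele frequencies with
# Wilson confidence intervals, and per-breed summary tables.

#' Exon-to-exon PCR product sizes
#'
#' An assay amplifying from one exon to a later exon yields a long product
#' from the genomic (intron-containing) template and a short product from
#' an intronless retrocopy template; the size gap equals the summed
#' intervening introns, and a short product therefore diagnoses the
#' presence of a retrocopy.
#'
#' @param gene the parental [GeneModel].
#' @param primer5Pos,primer3Pos mRNA coordinates of the amplicon bounds
#'   (first base of the forward primer, last base of the reverse primer).
#'   The two positions must lie in different exons, otherwise the assay
#'   cannot discriminate the templates.
#' @return named numeric vector `c(genomic = , spliced = )`, bp.
#' @examples
#' gm <- GeneModel("c", "+", c(1, 1101, 2101), c(100, 1200, 2300),
#'                 50, 240, mrna = strrep("ACGT", 100))
#' exonExonProductSizes(gm, 10, 350)  # genomic exceeds spliced by introns
#' @export
exonExonProductSizes <- function(gene, primer5Pos, primer3Pos) {
  p5 <- as.integer(primer5Pos); p3 <- as.integer(primer3Pos)
  if (p5 >= p3) stop("primer5Pos must precede primer3Pos (mRNA coordinates)",
                     call. = FALSE)
  e5 <- exonOfMrnaPos(gene, p5); e3 <- exonOfMrnaPos(gene, p3)
  if (e5 == e3)
    stop("primers lie in the same exon: assay cannot discriminate",
         call. = FALSE)
  spliced <- p3 - p5 + 1L
  g5 <- mrnaToGenomic(gene, p5); g3 <- mrnaToGenomic(gene, p3)
  genomic <- abs(g3 - g5) + 1L
  c(genomic = genomic, spliced = spliced)
}

#' Wilson score confidence interval for a proportion
#'
#' Preferred over the Wald interval for the small cohorts (n of 5-30
#' individuals) typical of targeted breed genotyping.
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
wilsonCi <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Allele frequency of a retrocopy in a cohort
#'
#' Diploid counting: frequency `= (het + 2 * homalt) / (2n)` where
#' `copies` gives each individual's retrocopy copy number (0, 1 or 2).
#'
#' @param copies integer vector of per-individual copy numbers.
#' @param conf confidence level for the Wilson interval.
#' @return a list: `n`, `het`, `homalt`, `frequency` (in `[0, 1]`),
#'   `ci` (Wilson interval on the allele counts).
#' @examples
#' alleleFrequency(c(2, 2, 1, 1, 0, 0, 0, 0, 0, 0))$frequency  # 0.3
#' @export
alleleFrequency <- function(copies, conf = 0.95) {
  if (length(copies) < 1L) stop("need at least one individual", call. = FALSE)
  if (!all(copies %in% 0:2))
    stop("copies must be 0, 1 or 2", call. = FALSE)
  n <- length(copies)
  het <- sum(copies == 1L)
  homalt <- sum(copies == 2L)
  alleles <- het + 2L * homalt
  freq <- alleles / (2L * n)
  list(n = n, het = het, homalt = homalt, frequency = freq,
       ci = wilsonCi(alleles, 2L * n, conf = conf))
}

#' Per-breed allele-frequency summary
#'
#' One row per (breed, marker): cohort size, het/homalt counts, allele
#' frequency (percent) and its Wilson 95% CI. Unknown breed labels pass
#' through verbatim.
#'
#' @param genotypes `data.frame` with columns `individual`, `breed`,
#'   `marker`, `copies`.
#' @return summary `data.frame`.
#' @examples
#' g <- data.frame(individual = 1:4, breed = "NSDTR", marker = "L3",
#'                 copies = c(1, 0, 0, 0))
#' screenSummary(g)$frequencyPct  # 12.5
#' @export
screenSummary <- function(genotypes) {
  needed <- c("individual", "breed", "marker", "copies")
  if (!all(needed %in% names(genotypes)))
    stop("genotype table needs columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (nrow(genotypes) == 0L)
    return(data.frame(breed = character(), marker = character(),
                      n = integer(), het = integer(), homalt = integer(),
                      frequencyPct = numeric(), ciLowerPct = numeric(),
                      ciUpperPct = numeric(), stringsAsFactors = FALSE))
  groups <- split(genotypes,
                  list(genotypes$breed, genotypes$marker), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    af <- alleleFrequency(g$copies)
    data.frame(breed = g$breed[1L], marker = g$marker[1L], n = af$n,
               het = af$het, homalt = af$homalt,
               frequencyPct = roundHalfUp(100 * af$frequency, 1L),
               ciLowerPct = roundHalfUp(100 * af$ci[["lower"]], 1L),
               ciUpperPct = roundHalfUp(100 * af$ci[["upper"]], 1L),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$breed, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genotype table from TSV
#'
#' @param path TSV with columns `individual`, `breed`, `marker`, `copies`.
#' @return validated `data.frame`.
#' @export
readGenotypes <- function(path) {
  g <- readTsv(path)
  needed <- c("individual", "breed", "marker", "copies")
  if (!all(needed %in% names(g)))
    stop("genotype table needs columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (!all(g$copies %in% 0:2))
    stop("copies must be 0, 1 or 2", call. = FALSE)
  g
}

#' Predicted products of a three-primer presence/absence assay
#'
#' The assay combines a flanking primer pair across the empty insertion
#' site with a shared primer at the retrocopy 3' end: the empty allele
#' yields the flank-to-flank product, the insertion allele the
#' flank-to-internal product, so each allele is read off by band size.
#'
#' @param flankProduct flank-to-flank product size on the empty allele, bp.
#' @param insertionProduct flank-to-internal-primer product size on the
#'   insertion allele, bp.
#' @return `data.frame` of genotype (0/1/2 copies) vs expected bands.
#' @export
threePrimerProducts <- function(flankProduct, insertionProduct) {
  data.frame(
    copies = 0:2,
    bands = c(sprintf("%d", flankProduct),
              sprintf("%d+%d", flankProduct, insertionProduct),
              sprintf("%d", insertionProduct)),
    stringsAsFactors = FALSE)
}
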