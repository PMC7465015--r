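# Top-level pipeline: simulate -> scan -> characterize -> compare ->
# genopop, driven by a single YAML configuration, with a provenance
# manifest so a rerun with the same config is verifiably identical.

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file with sections `sim` (passed to
#' [SimConfig()]), `genome` (passed to [buildGenome()]), `insertions`
#' (count, or a list of explicit truth records), `scan` (thresholds), and
#' input paths `ecrBed`, `populationVcf`, `genotypeTsv`. All referenced
#' paths must exist at validation time; validation failures abort before
#' any stage runs.
#'
#' @param path YAML config path.
#' @return validated config list (class `retroseekConfig`).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg, dir = dirname(normalizePath(path)))
}

#' @rdname readPipelineConfig
#' @param cfg a config list (as from [yaml::read_yaml]).
#' @param dir directory against which relative paths are resolved.
#' @export
validatePipelineConfig <- function(cfg, dir = ".") {
  for (key in c("ecrBed", "populationVcf", "genotypeTsv")) {
    if (is.null(cfg[[key]])) next
    p <- cfg[[key]]
    if (!file.exists(p)) p <- file.path(dir, cfg[[key]])
    if (!file.exists(p))
      stop("config path for '", key, "' does not exist: ", cfg[[key]],
           call. = FALSE)
    cfg[[key]] <- normalizePath(p)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$insertions <- cfg$insertions %||% 1L
  cfg$scan <- cfg$scan %||% list()
  structure(cfg, class = "retroseekConfig")
}

#' Run the full retrocopy pipeline
#'
#' Executes every stage into per-stage subdirectories of `outDir`:
#' `simulate/` (genome FASTA, SAM, truth BED/TSV), `scan/` (classified
#' pair counts, calls), `characterize/` (site reports), `compare/`
#' (variant classifications) and `genopop/` (breed frequency summary),
#' plus a `manifest.json` recording the package version, seed, thresholds
#' and the MD5 of every output. Any stage failure aborts with the stage
#' name; a rerun with the same config reproduces identical outputs.
#'
#' @param config a config list from [readPipelineConfig()] (or a path).
#' @param outDir output directory (created if needed).
#' @param seed optional seed overriding the config's.
#' @return (invisibly) a list with the per-stage results and the manifest.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!inherits(config, "retroseekConfig"))
    config <- validatePipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, fn) {
    d <- file.path(outDir, name)
    dir.create(d, showWarnings = FALSE)
    tryCatch(fn(d), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  simArgs <- config$sim %||% list()
  simArgs$seed <- config$seed
  simCfg <- do.call(SimConfig, simArgs)
  genomeArgs <- config$genome %||% list()
  if (!is.null(genomeArgs$chromLengths))
    genomeArgs$chromLengths <- unlist(genomeArgs$chromLengths)
  genome <- do.call(buildGenome, c(list(config = simCfg), genomeArgs))

  simRes <- stage("simulate", function(d) {
    planted <- genome
    nIns <- if (is.numeric(config$insertions)) config$insertions
            else length(config$insertions)
    for (i in seq_len(nIns)) {
      truth <- if (is.list(config$insertions)) {
        ins <- config$insertions[[i]]
        InsertionTruth(ins$chrom, ins$pos, tsdLen = ins$tsdLen %||% 13L,
                       strand = ins$strand %||% "+",
                       trunc5 = ins$trunc5 %||% 0L,
                       trunc3 = ins$trunc3 %||% 0L,
                       polyALen = ins$polyALen %||% 50L)
      } else randomInsertionTruth(planted, seed = childSeed(config$seed, i))
      planted <- plantRetrocopy(planted, truth)
    }
    sim <- simulateAlignments(planted, simCfg)
    writeGenomeFasta(planted, file.path(d, "reference.fa"), "reference")
    writeGenomeFasta(planted, file.path(d, "sample.fa"), "mutated")
    writeSam(sim, file.path(d, "alignments.sam"))
    writeTruthBed(planted, file.path(d, "truth_insertions.bed"))
    writeTruthPairs(sim, file.path(d, "truth_pairs.tsv"))
    list(planted = planted, sim = sim)
  })

  scanRes <- stage("scan", function(d) {
    res <- scanSample(file.path(outDir, "simulate", "alignments.sam"),
                      genome@gene,
                      insertMean = simCfg@insertMean,
                      insertSd = simCfg@insertSd,
                      minJunction = config$scan$minJunction %||% 3L,
                      minTrans = config$scan$minTrans %||% 3L,
                      verbose = TRUE)
    counts <- as.data.frame(table(factor(res$pairs$class,
                                         levels = SIGNAL_CLASSES)))
    names(counts) <- c("class", "n")
    writeTsv(counts, file.path(d, "pair_class_counts.tsv"))
    calls <- res$calls
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
                     start = GenomicRanges::start(calls),
                     end = GenomicRanges::end(calls),
                     status = calls$status,
                     nJunctionPairs = calls$nJunctionPairs,
                     nSplitReads = calls$nSplitReads,
                     nTransPairs = calls$nTransPairs,
                     orientation = calls$orientation)
    writeTsv(df, file.path(d, "calls.tsv"))
    if (length(calls))
      writeBedIntervals(GenomicRanges::granges(calls),
                        file.path(d, "calls.bed"))
    res
  })

  charRes <- stage("characterize", function(d) {
    planted <- simRes$planted
    layout <- insertionLayout(planted)
    reports <- lapply(seq_len(nrow(layout)), function(i) {
      li <- layout[i, ]
      mutSeq <- planted@mutated[[li$chrom]]
      ctx5 <- as.character(Biostrings::subseq(mutSeq,
        max(1L, li$Tp - li$tsdLen - 10L + 1L), li$Tp))
      j3 <- li$Tp + li$bodyLen + 1L
      ctx3 <- as.character(Biostrings::subseq(mutSeq, j3,
        min(length(mutSeq), j3 + li$tsdLen + 10L - 1L)))
      characterizeSite(sprintf("site%d", i), ctx5, ctx3,
                       strand = li$strand,
                       insertionInterval = list(chrom = li$chrom,
                                                start = li$T - li$tsdLen + 1L,
                                                end = li$T),
                       ecr = config$ecrBed)
    })
    writeSiteReports(reports, file.path(d, "site_reports.tsv"),
                     locations = sprintf("%s:%d", layout$chrom, layout$T))
    reports
  })

  cmpRes <- stage("compare", function(d) {
    planted <- simRes$planted
    layout <- insertionLayout(planted)
    gene <- planted@gene
    rows <- lapply(seq_along(planted@truths), function(i) {
      tr <- planted@truths[[i]]
      allele <- as.character(planted@alleles[[i]])
      # strip the TSD copies, orient to the mRNA strand
      body <- substr(allele, tr@tsdLen + 1L, nchar(allele) - tr@tsdLen)
      if (tr@strand == "-") body <- revcompChar(body)
      vars <- alignAndCall(body, gene)
      if (!is.null(config$populationVcf))
        vars <- classifyVariants(vars, config$populationVcf)
      else vars$classification <- rep("UNKNOWN", nrow(vars))
      if (nrow(vars)) vars$site <- sprintf("site%d", i)
      vars
    })
    vars <- do.call(rbind, rows)
    if (is.null(vars) || nrow(vars) == 0L)
      vars <- data.frame(site = character(), mrnaPos = integer(),
                         genomicPos = integer(), ref = character(),
                         alt = character(), kind = character(),
                         region = character(),
                         classification = character())
    writeTsv(vars, file.path(d, "variants.tsv"))
    vars
  })

  genoRes <- stage("genopop", function(d) {
    if (is.null(config$genotypeTsv)) return(NULL)
    g <- readGenotypes(config$genotypeTsv)
    s <- screenSummary(g)
    writeTsv(s, file.path(d, "breed_frequencies.tsv"))
    s
  })

  manifest <- list(
    package = "retroseek",
    version = as.character(utils::packageVersion("retroseek")),
    seed = config$seed,
    thresholds = list(minJunction = config$scan$minJunction %||% 3L,
                      minTrans = config$scan$minTrans %||% 3L),
    sim = list(readLen = simCfg@readLen, insertMean = simCfg@insertMean,
               insertSd = simCfg@insertSd, coverage = simCfg@coverage,
               errorRate = simCfg@errorRate),
    outputs = local({
      fs <- sort(list.files(outDir, recursive = TRUE, full.names = FALSE))
      fs <- fs[fs != "manifest.json"]
      md5 <- tools::md5sum(file.path(outDir, fs))
      stats::setNames(as.list(unname(md5)), fs)
    }))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(simulate = simRes, scan = scanRes,
                 characterize = charRes, compare = cmpRes,
                 genopop = genoRes, manifest = manifest))
}
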