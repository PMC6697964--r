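#' Run the full marker-development pipeline on synthetic data
#'
#' Orchestrates simulate -> mine -> annotate -> classify -> summarize in
#' dependency order: generates transcripts with planted ORFs, plants SSRs and
#' SNPs, mines and region-classifies SSRs, computes the SNP substitution
#' spectrum, classifies differentially expressed genes from a simulated
#' two-condition count table, summarizes germplasm diversity from a simulated
#' band matrix, and genotypes simulated melt curves. Identical config and
#' seed give byte-identical tabular outputs.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognised top-level keys: `seed`, `outDir`, and per-stage blocks
#'   `simulate` (with sub-blocks `transcripts`, `ssrs`, `snps`, `counts`,
#'   `alleles`, `melt`), `ssr`, `orf`, `snp`, `hrm`. Unknown keys are a
#'   validation error before any stage runs.
#' @return A `RunReport` list with elements `ssrSummary`, `spectrum`,
#'   `diversity`, `degSummary`, `hrmCalls`, `truth` (all planted truth
#'   tables), `artifacts` (per-record tables) and `provenance` (seed, config
#'   hash, package version). When `outDir` is set the artifact files are
#'   written via [writeReport()].
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validateConfig(config)
  seed <- config$seed %||% 1L
  simCfg <- config$simulate %||% list()
  message("stage simulate/transcripts")
  tr <- do.call(generateTranscripts,
                c(list(seed = seed),
                  simCfg$transcripts %||% list(nTranscripts = 60L)))
  message("  ", length(tr$transcripts), " transcripts, ",
          nrow(tr$orfTruth), " planted ORFs")
  ssrCfg <- simCfg$ssrs %||%
    list(motifMix = list(GAA = 6L, AG = 4L, ATCT = 2L))
  ssrCfg$motifMix <- unlist(ssrCfg$motifMix)
  planted <- do.call(plantSSRs,
                     c(list(transcripts = tr$transcripts,
                            orfTruth = tr$orfTruth, seed = seed), ssrCfg))
  message("stage simulate/ssrs: ", nrow(planted$ssrTruth), " loci planted")
  ssrTruthGr <- GenomicRanges::GRanges(
    planted$ssrTruth$transcriptId,
    IRanges::IRanges(planted$ssrTruth$start, planted$ssrTruth$end))
  snpCfg <- simCfg$snps %||% list(n = 150L)
  snps <- do.call(plantSNPs,
                  c(list(transcripts = planted$transcripts,
                         avoid = ssrTruthGr, seed = seed), snpCfg))
  message("stage simulate/snps: ", nrow(snps$truth), " variants planted")

  message("stage mine-ssr")
  loci <- findSSRs(planted$transcripts)
  orfs <- annotateOrfs(planted$transcripts,
                       minLenNt = (config$orf %||% list())$minLenNt %||% 90L)
  loci <- classifyFeatureRegions(loci, orfs)
  totalBp <- sum(nchar(asSequenceCharacters(planted$transcripts)))
  ssrSummary <- summarizeSSRs(loci, totalBp)
  message("  ", ssrSummary$totalLoci, " loci mined, ", length(orfs),
          " ORFs annotated")

  message("stage classify-snp")
  vcfPath <- tempfile(fileext = ".vcf")
  writeVcf(snps, vcfPath)
  parsed <- readVariants(vcfPath)
  unlink(vcfPath)
  thr <- do.call(filterThresholds, config$snp %||% list())
  flt <- filterVariants(parsed$records, thr)
  spectrum <- snpSpectrum(flt$retained, orfs)
  message("  ", nrow(parsed$records), " records in, ",
          nrow(flt$retained), " retained")

  message("stage express")
  lens <- setNames(nchar(asSequenceCharacters(planted$transcripts)),
                   names(asSequenceCharacters(planted$transcripts)))
  cntCfg <- simCfg$counts %||% list(nUp = 5L, nDown = 5L)
  if (!is.null(cntCfg$libSizes)) cntCfg$libSizes <- unlist(cntCfg$libSizes)
  se <- do.call(simulateCounts,
                c(list(transcriptLengths = lens, seed = seed), cntCfg))
  degs <- classifyDegs(se)
  message("  ", degs$summary$nUp, " up, ", degs$summary$nDown, " down")

  message("stage diversity")
  am <- do.call(simulateAlleleMatrix,
                c(list(seed = seed), simCfg$alleles %||% list()))
  diversity <- summarizeDiversity(am$matrix)

  message("stage hrm-call")
  meltCfg <- simCfg$melt %||%
    list(genotypes = c("A/A", "G/G", "A/G"), noiseSd = 0.005)
  curves <- lapply(seq_along(meltCfg$genotypes), function(i) {
    simulateGenotypeCurve(meltCfg$genotypes[i],
                          noiseSd = meltCfg$noiseSd %||% 0.005,
                          sampleId = sprintf("S%02d_%s", i,
                                             gsub("/", "", meltCfg$genotypes[i])),
                          seed = seed)
  })
  hrmCalls <- callGenotypes(curves)
  message("  ", nrow(hrmCalls), " curves genotyped")

  report <- structure(list(
    ssrSummary = ssrSummary,
    spectrum = spectrum,
    diversity = diversity,
    degSummary = degs$summary,
    hrmCalls = hrmCalls,
    truth = list(orf = tr$orfTruth, ssr = planted$ssrTruth,
                 snp = snps$truth,
                 deg = as.data.frame(SummarizedExperiment::rowData(se)),
                 alleleFreqs = am$truth),
    artifacts = list(transcripts = planted$transcripts, ssrLoci = loci,
                     orfs = orfs, variants = flt$retained,
                     rejectedVariants = flt$rejected, degRecords = degs,
                     alleleMatrix = am$matrix, curves = curves),
    provenance = list(seed = seed, configHash = configHash(config),
                      package = as.character(utils::packageVersion(
                        "TranscriptMarkers")))),
    class = "RunReport")
  if (!is.null(config$outDir)) writeReport(report, config$outDir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validateConfig <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  known <- c("seed", "outDir", "simulate", "ssr", "orf", "snp", "diversity",
             "expression", "hrm", "report")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("validation error: unknown config key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  simKnown <- c("transcripts", "ssrs", "snps", "counts", "alleles", "melt")
  badSim <- setdiff(names(config$simulate %||% list()), simKnown)
  if (length(badSim))
    stop("validation error: unknown simulate key(s): ",
         paste(badSim, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$configHash, 1, 8), ")\n", sep = "")
  print(x$ssrSummary)
  print(x$spectrum)
  print(x$diversity)
  cat("DEGs: ", x$degSummary$nUp, " up, ", x$degSummary$nDown, " down, ",
      x$degSummary$nUnchanged, " unchanged, ", x$degSummary$nUndefined,
      " undefined\n", sep = "")
  cat("HRM calls:\n")
  print(x$hrmCalls, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes the per-record tables (SSR loci, ORFs, retained variants, DEG
#' records, allele matrix, HRM calls, diversity outputs) plus a
#' human-readable `summary.txt`. Rounding is applied only at write time.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(x) { paths <<- c(paths, x); x }
  writeFasta(report$artifacts$transcripts, p(file.path(dir,
                                                       "transcripts.fa")))
  writeSsrTable(report$artifacts$ssrLoci, p(file.path(dir, "ssr_loci.tsv")))
  writeOrfTable(report$artifacts$orfs, p(file.path(dir, "orfs.tsv")))
  write.table(report$artifacts$variants,
              p(file.path(dir, "variants_retained.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSpectrum(report$spectrum, p(file.path(dir, "snp_spectrum.tsv")))
  writeDegTable(report$artifacts$degRecords,
                p(file.path(dir, "deg_table.tsv")))
  write.table(report$artifacts$alleleMatrix,
              p(file.path(dir, "allele_matrix.tsv")), sep = "\t",
              quote = FALSE, col.names = NA)
  writeDiversity(report$diversity, p(file.path(dir, "diversity")))
  write.table(report$hrmCalls, p(file.path(dir, "hrm_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(p(file.path(dir, "summary.txt")), "w")
  sink(con); print(report); sink(); close(con)
  invisible(paths)
}
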