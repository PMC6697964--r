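#' Plant single-nucleotide substitutions and emit a truth VCF
#'
#' Chooses `n` distinct transcript positions, substitutes the reference base
#' with a transition (A<->G, C<->T) with probability `tsFraction` or a random
#' transversion otherwise, assigns zygosity HET with probability
#' `hetFraction`, and draws read depth and mapping quality uniformly from the
#' given ranges. The default DP/MQ ranges straddle the depth/quality filter
#' thresholds (20/200/10) so filtering has bite on synthetic data.
#'
#' @param transcripts reference `DNAStringSet` (or named character).
#' @param n number of SNPs to plant.
#' @param tsFraction probability a planted SNP is a transition (default 0.61).
#' @param hetFraction probability of a heterozygous call (default 0.0092).
#' @param dpRange integer read-depth range (uniform; default `c(10, 250)`).
#' @param mqRange mapping-quality range (uniform; default `c(0, 60)`).
#' @param avoid optional `GRanges` (e.g. planted SSR loci) whose positions
#'   are never mutated.
#' @param seed integer seed.
#' @return A list: `truth` (data.frame `transcriptId`, `pos` (1-based),
#'   `refBase`, `altBase`, `type`, `zygosity`, `depth`, `mapQuality`),
#'   `altTranscripts` (`DNAStringSet` with homozygous alternates substituted),
#'   and `vcfLines` (character, a VCF v4.2 document; see [writeVcf()]).
#' @export
plantSNPs <- function(transcripts, n, tsFraction = 0.61,
                      hetFraction = 0.0092, dpRange = c(10L, 250L),
                      mqRange = c(0, 60), avoid = NULL, seed = 1L) {
  stopifnot(tsFraction >= 0, tsFraction <= 1,
            hetFraction >= 0, hetFraction <= 1, n >= 0)
  withSeed(seedFor(seed, "plant_snps"), {
    seqs <- asSequenceCharacters(transcripts)
    lens <- nchar(seqs)
    ## candidate positions: all (transcript, pos) pairs outside `avoid`
    pool <- data.frame(
      tid = rep(names(seqs), lens),
      pos = unlist(lapply(lens, seq_len), use.names = FALSE))
    if (!is.null(avoid) && length(avoid) > 0L) {
      avoidKey <- unlist(lapply(seq_along(avoid), function(i) {
        paste0(as.character(GenomicRanges::seqnames(avoid))[i], ":",
               seq(GenomicRanges::start(avoid)[i],
                   GenomicRanges::end(avoid)[i]))
      }))
      pool <- pool[!(paste0(pool$tid, ":", pool$pos) %in% avoidKey), ]
    }
    if (n > nrow(pool))
      stop("n exceeds the number of available positions")
    pick <- pool[sample.int(nrow(pool), n), ]
    pick <- pick[order(pick$tid, pick$pos), ]
    ref <- substring(seqs[pick$tid], pick$pos, pick$pos)
    isTs <- runif(n) < tsFraction
    tsPartner <- c(A = "G", G = "A", C = "T", T = "C")
    alt <- character(n)
    for (i in seq_len(n)) {
      alt[i] <- if (isTs[i]) tsPartner[[ref[i]]] else {
        sample(setdiff(BASES, c(ref[i], tsPartner[[ref[i]]])), 1L)
      }
    }
    zyg <- ifelse(runif(n) < hetFraction, "HET", "HOM")
    truth <- data.frame(
      transcriptId = pick$tid, pos = pick$pos, refBase = ref, altBase = alt,
      type = ifelse(isTs, "TRANSITION", "TRANSVERSION"), zygosity = zyg,
      depth = dpRange[1] + sample.int(dpRange[2] - dpRange[1] + 1L, n,
                                      replace = TRUE) - 1L,
      mapQuality = round(runif(n, mqRange[1], mqRange[2]), 1),
      row.names = NULL)
    altSeqs <- seqs
    hom <- truth[truth$zygosity == "HOM", ]
    for (i in seq_len(nrow(hom))) {
      substr(altSeqs[[hom$transcriptId[i]]], hom$pos[i], hom$pos[i]) <-
        hom$altBase[i]
    }
    list(truth = truth,
         altTranscripts = Biostrings::DNAStringSet(altSeqs),
         vcfLines = vcfDocument(truth, lens))
  })
}

vcfDocument <- function(truth, contigLengths) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=TranscriptMarkers-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
            contigLengths),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE", sep = "\t"))
  if (nrow(truth) == 0L) return(header)
  gt <- ifelse(truth$zygosity == "HET", "0/1", "1/1")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;MQ=%.1f\tGT\t%s",
                  truth$transcriptId, truth$pos, truth$refBase,
                  truth$altBase, truth$depth, truth$mapQuality, gt)
  c(header, body)
}

#' Write a planted-SNP truth set as VCF v4.2
#'
#' @param planted result of [plantSNPs()] (or its `vcfLines`).
#' @param path output path (plain text).
#' @return The path, invisibly.
#' @export
writeVcf <- function(planted, path) {
  lines <- if (is.list(planted)) planted$vcfLines else planted
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a two-condition count table with planted DEGs
#'
#' Counts are drawn from a negative binomial model (mean/dispersion
#' parameterisation): each transcript gets a lognormal baseline mean around
#' `baseMean`, planted up-regulated genes have their treated-condition mean
#' multiplied by `2^log2fc` and down-regulated genes divided by it, and the
#' per-condition mean is scaled by the library size ratio.
#'
#' @param transcriptLengths named integer vector of transcript lengths (bp).
#' @param nUp,nDown numbers of planted up-/down-regulated transcripts
#'   (`nUp + nDown <=` number of transcripts).
#' @param baseMean baseline expected count (must be > 0).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libSizes numeric `c(control=, treated=)` total mappable reads.
#' @param log2fc planted effect size in log2 units (default 2 = 4-fold).
#' @param seed integer seed.
#' @return A `SummarizedExperiment`: assay `counts` (transcripts x
#'   {control, treated}), `rowData` columns `length` and `truth`
#'   (`"up"`/`"down"`/`"unchanged"`), and `metadata(x)$libSizes`.
#' @export
simulateCounts <- function(transcriptLengths, nUp, nDown, baseMean = 100,
                           dispersion = 0.1,
                           libSizes = c(control = 1e6, treated = 1e6),
                           log2fc = 2, seed = 1L) {
  nT <- length(transcriptLengths)
  if (baseMean <= 0) stop("baseMean must be positive")
  if (nUp + nDown > nT) stop("nUp + nDown exceeds the number of transcripts")
  withSeed(seedFor(seed, "simulate_counts"), {
    ids <- names(transcriptLengths)
    truth <- rep("unchanged", nT)
    deg <- sample.int(nT, nUp + nDown)
    truth[deg[seq_len(nUp)]] <- "up"
    if (nDown > 0) truth[deg[nUp + seq_len(nDown)]] <- "down"
    mu0 <- exp(rnorm(nT, log(baseMean), 0.5))
    fc <- ifelse(truth == "up", 2^log2fc,
                 ifelse(truth == "down", 2^(-log2fc), 1))
    sizeFactor <- libSizes / mean(libSizes)
    size <- 1 / dispersion
    counts <- cbind(
      control = rnbinom(nT, mu = mu0 * sizeFactor[["control"]], size = size),
      treated = rnbinom(nT, mu = mu0 * fc * sizeFactor[["treated"]],
                        size = size))
    rownames(counts) <- ids
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(length = unname(transcriptLengths),
                                     truth = truth, row.names = ids),
      colData = S4Vectors::DataFrame(condition = c("control", "treated"),
                                     row.names = c("control", "treated")),
      metadata = list(libSizes = libSizes))
  })
}

#' Simulate a band presence/absence matrix with known allele frequencies
#'
#' Each locus gets an allele count drawn from `allelesPerLocusDist` and
#' allele frequencies drawn uniformly on the simplex; every genotype then
#' carries the band of one allele per locus (dominant scoring of a
#' predominantly homozygous, self-pollinating panel), or no band at all with
#' probability `nullRate` (null allele).
#'
#' @param nLoci,nGenotypes panel dimensions (defaults 31 loci x 27
#'   genotypes).
#' @param allelesPerLocusDist named numeric vector: allele count (1-10) ->
#'   probability.
#' @param nullRate per-genotype-per-locus null-allele probability.
#' @param frequencies optional list of per-locus allele frequency vectors
#'   (length `nLoci`), overriding the random allele counts and frequencies
#'   (e.g. `list(c(0.5, 0.5))` for one locus with two equifrequent alleles).
#' @param seed integer seed.
#' @return A list: `matrix` (binary genotypes x bands, band columns named
#'   `"locus:allele"`) and `truth` (list per locus of the frequencies used).
#' @export
simulateAlleleMatrix <- function(nLoci = 31L, nGenotypes = 27L,
                                 allelesPerLocusDist = c("1" = 0.10,
                                                         "2" = 0.25,
                                                         "3" = 0.35,
                                                         "4" = 0.20,
                                                         "5" = 0.10),
                                 nullRate = 0, frequencies = NULL,
                                 seed = 1L) {
  if (nGenotypes < 1L) stop("need at least one genotype")
  ks <- as.integer(names(allelesPerLocusDist))
  if (any(ks < 1L | ks > 10L)) stop("alleles per locus must be in 1..10")
  if (!is.null(frequencies)) {
    if (length(frequencies) != nLoci)
      stop("frequencies must have one entry per locus")
    if (any(vapply(frequencies, length, integer(1)) > 10L))
      stop("alleles per locus must be in 1..10")
  }
  withSeed(seedFor(seed, "simulate_allele_matrix"), {
    lociIds <- sprintf("L%03d", seq_len(nLoci))
    genotypes <- sprintf("G%02d", seq_len(nGenotypes))
    truth <- list()
    mat <- NULL
    for (l in seq_len(nLoci)) {
      if (!is.null(frequencies)) {
        f <- frequencies[[l]] / sum(frequencies[[l]])
        k <- length(f)
      } else {
        k <- ks[sample.int(length(ks), 1L, prob = allelesPerLocusDist)]
        f <- -log(runif(k)); f <- f / sum(f)   # uniform on the simplex
      }
      truth[[lociIds[l]]] <- f
      draw <- sample.int(k, nGenotypes, replace = TRUE, prob = f)
      isNull <- runif(nGenotypes) < nullRate
      block <- matrix(0L, nGenotypes, k,
                      dimnames = list(genotypes,
                                      paste0(lociIds[l], ":a", seq_len(k))))
      block[cbind(which(!isNull), draw[!isNull])] <- 1L
      mat <- if (is.null(mat)) block else cbind(mat, block)
    }
    list(matrix = mat, truth = truth)
  })
}
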