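test_that("generateTranscripts is deterministic and respects its bounds", {
  a <- generateTranscripts(20, seed = 5)
  b <- generateTranscripts(20, seed = 5)
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(a$orfTruth, b$orfTruth)
  lens <- nchar(as.character(a$transcripts))
  expect_true(all(lens >= 280 & lens <= 6445))
  expect_error(generateTranscripts(5, lengthRange = c(600, 400)),
               "degenerate")
  expect_error(generateTranscripts(5, lengthRange = c(100, 400)), ">= 200")
  # FASTA bytes identical under equal seeds
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeFasta(a$transcripts, f1)
  writeFasta(b$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(nchar(readLines(f1)) <= 60))
})

test_that("planted ORFs are exactly recoverable and UTRs are ORF-free", {
  g <- generateTranscripts(50, orfFraction = 1, seed = 9)
  expect_equal(nrow(g$orfTruth), 50L)
  ann <- annotateOrfs(g$transcripts)
  expect_equal(length(ann), 50L)
  ord <- match(g$orfTruth$transcriptId,
               as.character(GenomicRanges::seqnames(ann)))
  expect_equal(GenomicRanges::start(ann)[ord], g$orfTruth$cdsStart)
  expect_equal(GenomicRanges::end(ann)[ord], g$orfTruth$cdsEnd)
  expect_true(all(g$orfTruth$lengthNt >= 300))
  expect_true(all(g$orfTruth$lengthNt %% 3 == 0))
  # no-ORF transcripts really have none
  g0 <- generateTranscripts(10, orfFraction = 0, seed = 9)
  expect_equal(length(annotateOrfs(g0$transcripts)), 0L)
})

test_that("plantSSRs plants re-extractable, maximal, non-overlapping loci", {
  g <- generateTranscripts(25, orfFraction = 1, seed = 3)
  p <- plantSSRs(g$transcripts, g$orfTruth, motifMix = c(AAG = 10),
                 seed = 3)
  tr <- p$ssrTruth
  expect_equal(nrow(tr), 10L)
  seqs <- as.character(p$transcripts)
  for (i in seq_len(nrow(tr))) {
    s <- seqs[[tr$transcriptId[i]]]
    expect_equal(substr(s, tr$start[i], tr$end[i]),
                 strrep(tr$motif[i], tr$repeatCount[i]))
    # not extendable by one unit in either direction
    pLen <- nchar(tr$motif[i])
    expect_false(substr(s, tr$start[i] - pLen, tr$start[i] - 1) ==
                   tr$motif[i])
    expect_false(substr(s, tr$end[i] + 1, tr$end[i] + pLen) == tr$motif[i])
    expect_equal(tr$end[i] - tr$start[i] + 1L,
                 pLen * tr$repeatCount[i])
  }
  # per-transcript loci do not abut or overlap
  for (tid in unique(tr$transcriptId)) {
    d <- tr[tr$transcriptId == tid, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)] + 1))
  }
})

test_that("plantSSRs honours the requested region mix exactly", {
  g <- generateTranscripts(30, orfFraction = 1, seed = 13)
  p <- plantSSRs(g$transcripts, g$orfTruth, motifMix = c(GAA = 12, CTG = 8),
                 regionMix = c(CDS = 0.68, FIVE_UTR = 0.16,
                               THREE_UTR = 0.16),
                 seed = 13)
  loci <- classifyFeatureRegions(findSSRs(p$transcripts),
                                 annotateOrfs(p$transcripts))
  mined <- as.data.frame(loci)
  mined <- mined[order(mined$seqnames, mined$start), ]
  tr <- p$ssrTruth[order(p$ssrTruth$transcriptId, p$ssrTruth$start), ]
  # downstream classifier's region agrees with truth with 0 mismatches
  expect_equal(nrow(mined), nrow(tr))
  expect_equal(mined$region, tr$region)
  # region placement errors are raised when no ORF exists anywhere
  g0 <- generateTranscripts(5, orfFraction = 0, seed = 13)
  expect_error(plantSSRs(g0$transcripts, g0$orfTruth,
                         motifMix = c(GAA = 2)), "no transcript has an ORF")
})

test_that("plantSNPs writes a consistent truth VCF with the requested
           spectrum", {
  g <- generateTranscripts(40, orfFraction = 1, seed = 21)
  n <- 1845
  s <- plantSNPs(g$transcripts, n, tsFraction = 0.61, hetFraction = 0,
                 seed = 21)
  expect_equal(nrow(s$truth), n)
  expect_true(all(s$truth$zygosity == "HOM"))
  expect_true(all(s$truth$refBase != s$truth$altBase))
  # REF matches the reference transcript at POS (1-based)
  seqs <- as.character(g$transcripts)
  expect_true(all(substring(seqs[s$truth$transcriptId], s$truth$pos,
                            s$truth$pos) == s$truth$refBase))
  # realized Ts count inside the exact binomial 99% interval
  tsCount <- sum(s$truth$type == "TRANSITION")
  ci <- qbinom(c(0.005, 0.995), n, 0.61)
  expect_gte(tsCount, ci[1])
  expect_lte(tsCount, ci[2])
  # homozygous alternates really substituted
  alt <- as.character(s$altTranscripts)
  expect_true(all(substring(alt[s$truth$transcriptId], s$truth$pos,
                            s$truth$pos) == s$truth$altBase))
  # determinism
  s2 <- plantSNPs(g$transcripts, n, tsFraction = 0.61, hetFraction = 0,
                  seed = 21)
  expect_identical(s$vcfLines, s2$vcfLines)
  expect_error(plantSNPs(g$transcripts[1], 10^7, seed = 1),
               "exceeds")
})

test_that("simulateCounts plants recoverable fold-change truth", {
  lens <- setNames(rep(1000L, 60), sprintf("T%02d", 1:60))
  se <- simulateCounts(lens, nUp = 8, nDown = 8, baseMean = 200,
                       dispersion = 0.05, seed = 2)
  truth <- SummarizedExperiment::rowData(se)$truth
  expect_equal(sum(truth == "up"), 8L)
  expect_equal(sum(truth == "down"), 8L)
  cnt <- SummarizedExperiment::assay(se)
  expect_true(all(cnt >= 0))
  # no planted genes -> all 'unchanged'
  se0 <- simulateCounts(lens, 0, 0, seed = 2)
  expect_true(all(SummarizedExperiment::rowData(se0)$truth == "unchanged"))
  # determinism
  se2 <- simulateCounts(lens, nUp = 8, nDown = 8, baseMean = 200,
                        dispersion = 0.05, seed = 2)
  expect_identical(SummarizedExperiment::assay(se),
                   SummarizedExperiment::assay(se2))
  expect_error(simulateCounts(lens, 1, 1, baseMean = -5), "positive")
  expect_error(simulateCounts(lens, 40, 40), "exceeds")
})

test_that("simulateMeltCurve builds the stated two-state model", {
  # single species, no noise: monotone non-increasing
  cv <- simulateMeltCurve(80, noiseSd = 0, seed = 1)
  expect_s4_class(cv, "MeltCurve")
  expect_true(all(diff(fluorescence(cv)) <= 1e-9))
  # two species 2 C apart: exactly two local maxima in -dF/dT
  cv2 <- simulateMeltCurve(c(79, 81), weights = c(0.5, 0.5), noiseSd = 0,
                           seed = 1)
  ff <- fluorescence(cv2); tt <- temperatures(cv2)
  d <- -diff(ff) / diff(tt)[1]
  # strict local maxima of the analytic negative derivative, above the
  # baseline-slope floor (the sloped baselines give a small constant -dF/dT
  # everywhere)
  mid <- d[2:(length(d) - 1)]
  peaks <- sum(mid > d[1:(length(d) - 2)] & mid > d[3:length(d)] &
                 mid > 0.1 * max(d))
  expect_equal(peaks, 2L)
  # validation
  expect_error(simulateMeltCurve(c(79, 81), weights = c(0.6, 0.5)),
               "sum to 1")
  expect_error(simulateMeltCurve(80, tempGrid = seq(76, 95, 0.1)),
               "margin")
  # genotype auto-assignment respects the A/A < T/T < C/C < G/G order
  tms <- homoduplexTm(c("A", "T", "C", "G"))
  expect_true(all(diff(tms) > 0))
})

test_that("simulateAlleleMatrix records the frequencies it uses", {
  am <- simulateAlleleMatrix(nLoci = 12, nGenotypes = 40, seed = 8)
  expect_true(all(am$matrix %in% c(0L, 1L)))
  expect_equal(length(am$truth), 12L)
  # every genotype has exactly one band per locus when nullRate = 0
  loci <- sub(":.*$", "", colnames(am$matrix))
  for (l in unique(loci)) {
    expect_true(all(rowSums(am$matrix[, loci == l, drop = FALSE]) == 1L))
  }
  # single allele, no nulls -> PIC exactly 0
  am1 <- simulateAlleleMatrix(nLoci = 3, nGenotypes = 10,
                              allelesPerLocusDist = c("1" = 1), seed = 8)
  d <- summarizeDiversity(am1$matrix)
  expect_equal(d$locusStats$pic, rep(0, 3))
  # determinism and validation
  am2 <- simulateAlleleMatrix(nLoci = 12, nGenotypes = 40, seed = 8)
  expect_identical(am$matrix, am2$matrix)
  expect_error(simulateAlleleMatrix(nGenotypes = 0), "at least one")
})

test_that("estimated PIC converges to the truth-frequency PIC", {
  # 2 equifrequent alleles, no nulls: estimated PIC -> 0.5 as n grows
  picAt <- function(n) {
    am <- simulateAlleleMatrix(nLoci = 1, nGenotypes = n,
                               frequencies = list(c(0.5, 0.5)), seed = 99)
    picValue(locusFrequencies(am$matrix, "L001"))
  }
  errSmall <- abs(picAt(50) - 0.5)
  errLarge <- abs(picAt(5000) - 0.5)
  expect_lt(errLarge, 0.005)
  expect_lte(errLarge, errSmall + 1e-12)
  # random-frequency locus: estimate matches the planted truth
  am <- simulateAlleleMatrix(nLoci = 1, nGenotypes = 4000,
                             allelesPerLocusDist = c("3" = 1), seed = 7)
  f <- am$truth[[1]]
  est <- locusFrequencies(am$matrix, "L001")
  expect_lt(max(abs(sort(est) - sort(f))), 0.03)
  expect_lt(abs(picValue(est) - picValue(f)), 0.03)
})
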