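makeRecords <- function(n, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(transcriptId = sprintf("T%04d", sample(200, n, replace = TRUE)),
             pos = sample(1000, n, replace = TRUE), refBase = ref,
             altBase = unname(alt),
             depth = sample(0:300, n, replace = TRUE),
             mapQuality = round(runif(n, 0, 60), 1),
             zygosity = sample(c("HOM", "HET"), n, replace = TRUE,
                               prob = c(0.95, 0.05)))
}

test_that("filterVariants applies inclusive 20/200/10 boundaries", {
  rec <- data.frame(transcriptId = "t", pos = 1:6, refBase = "A",
                    altBase = "G",
                    depth = c(19, 20, 200, 201, 100, 100),
                    mapQuality = c(30, 30, 10, 30, 9, NA),
                    zygosity = "HOM")
  out <- filterVariants(rec, filterThresholds())
  expect_equal(out$retained$pos, c(2L, 3L))     # 20 and 200/MQ10 retained
  expect_equal(out$rejected$reason[out$rejected$pos == 1], "low-depth")
  expect_equal(out$rejected$reason[out$rejected$pos == 4], "high-depth")
  expect_equal(out$rejected$reason[out$rejected$pos == 5], "low-mapq")
  expect_equal(out$rejected$reason[out$rejected$pos == 6], "missing-field")
  expect_error(filterThresholds(minDepth = 300, maxDepth = 200), "<=")
})

test_that("filter decisions equal a per-record oracle on 10,000 records", {
  rec <- makeRecords(10000, seed = 5)
  out <- filterVariants(rec, filterThresholds())
  oracle <- vapply(seq_len(nrow(rec)), function(i) {
    d <- rec$depth[i]; q <- rec$mapQuality[i]
    !is.na(d) && !is.na(q) && d >= 20 && d <= 200 && q >= 10
  }, logical(1))
  expect_equal(nrow(out$retained), sum(oracle))
  expect_equal(sort(paste(out$retained$transcriptId, out$retained$pos)),
               sort(paste(rec$transcriptId, rec$pos)[oracle]))
  expect_equal(nrow(out$retained) + nrow(out$rejected), nrow(rec))
})

test_that("substitutionType separates transitions from transversions", {
  expect_equal(substitutionType("A", "G")$type, "TRANSITION")
  expect_equal(substitutionType("G", "A")$type, "TRANSITION")
  expect_equal(substitutionType("C", "T")$type, "TRANSITION")
  expect_equal(substitutionType("A", "T")$type, "TRANSVERSION")
  expect_equal(substitutionType("A", "G")$label, "A/G")
  expect_error(substitutionType("A", "A"), "differ")
  expect_error(substitutionType("A", "N"), "A/C/G/T")
  # complement invariance of transition status
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_equal(substitutionType(r, a)$type,
                 substitutionType(comp[[r]], comp[[a]])$type)
  }
})

test_that("hrmClass maps the four melting classes", {
  expect_equal(hrmClass("C", "T"), "I")
  expect_equal(hrmClass("G", "A"), "I")
  expect_equal(hrmClass("C", "A"), "II")
  expect_equal(hrmClass("G", "T"), "II")
  expect_equal(hrmClass("C", "G"), "III")
  expect_equal(hrmClass("A", "T"), "IV")
  # symmetric in the base pair
  expect_equal(hrmClass("T", "C"), "I")
  expect_error(hrmClass("A", "A"), "differ")
})

test_that("snpSpectrum reproduces printed ratio and share examples", {
  # 1129 transitions + 716 transversions -> Ts/Tv 1.58 at 2 decimals
  rec <- data.frame(
    transcriptId = "t", pos = seq_len(1845),
    refBase = c(rep("A", 1129), rep("A", 716)),
    altBase = c(rep("G", 1129), rep("T", 716)),
    depth = 50, mapQuality = 30, zygosity = "HOM")
  sp <- snpSpectrum(rec)
  expect_equal(sp$tsCount, 1129L)
  expect_equal(sp$tvCount, 716L)
  expect_equal(round(sp$tsTvRatio, 2), 1.58)
  expect_equal(sp$shares$ts, 61.2)
  # conservation: directional counts sum to the record count
  expect_equal(sum(sp$directional), nrow(rec))
  # all-transition input: undefined ratio marker
  spTs <- snpSpectrum(rec[seq_len(10), ])
  expect_true(is.na(spTs$tsTvRatio))
  # empty input: all-zero spectrum
  sp0 <- snpSpectrum(rec[0, ])
  expect_equal(sp0$total, 0L)
  expect_true(is.na(sp0$tsTvRatio))
})

test_that("spectrum region counts flow through the ORF classifier", {
  g <- generateTranscripts(20, orfFraction = 0.8, seed = 31)
  s <- plantSNPs(g$transcripts, 300, seed = 31)
  orfs <- annotateOrfs(g$transcripts)
  sp <- snpSpectrum(s$truth, orfs)
  expect_equal(sum(sp$regionCounts), 300L)
  # per-record oracle for the region assignment
  orfIds <- as.character(GenomicRanges::seqnames(orfs))
  want <- table(vapply(seq_len(300), function(i) {
    j <- match(s$truth$transcriptId[i], orfIds)
    classifyRegion(if (is.na(j)) NULL else orfs[j], s$truth$pos[i],
                   s$truth$pos[i])
  }, character(1)))
  expect_equal(sp$regionCounts[names(want)],
               setNames(as.integer(want), names(want)))
  # transcripts without ORF get UNCLASSIFIED
  expect_gt(sp$regionCounts[["UNCLASSIFIED"]], 0L)
})

test_that("VCF round-trip preserves records and skips non-SNVs", {
  g <- generateTranscripts(10, orfFraction = 1, seed = 41)
  s <- plantSNPs(g$transcripts, 120, hetFraction = 0.2, seed = 41)
  f <- withr::local_tempfile(fileext = ".vcf")
  lines <- s$vcfLines
  # inject an indel, an MNP and a multi-allelic line
  tid <- s$truth$transcriptId[1]
  extra <- c(
    sprintf("%s\t1\t.\tA\tAT\t.\tPASS\tDP=50;MQ=30.0\tGT\t1/1", tid),
    sprintf("%s\t2\t.\tAC\tGT\t.\tPASS\tDP=50;MQ=30.0\tGT\t1/1", tid),
    sprintf("%s\t3\t.\tA\tG,T\t.\tPASS\tDP=50;MQ=30.0\tGT\t1/1", tid))
  writeLines(c(lines, extra), f)
  rv <- readVariants(f)
  expect_equal(nrow(rv$records), 121L)   # 120 + first ALT of multiallelic
  expect_equal(rv$skipped[["indel"]], 1L)
  expect_equal(rv$skipped[["mnp"]], 1L)
  expect_equal(rv$skipped[["multiallelic-extra-alt"]], 1L)
  got <- rv$records[rv$records$pos %in% s$truth$pos &
                      paste(rv$records$transcriptId, rv$records$pos) %in%
                      paste(s$truth$transcriptId, s$truth$pos), ]
  expect_equal(nrow(got), 120L)
  ord <- order(got$transcriptId, got$pos)
  tr <- s$truth[order(s$truth$transcriptId, s$truth$pos), ]
  expect_equal(got$refBase[ord], tr$refBase)
  expect_equal(got$altBase[ord], tr$altBase)
  expect_equal(got$zygosity[ord], tr$zygosity)
  expect_equal(got$depth[ord], tr$depth)
})
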