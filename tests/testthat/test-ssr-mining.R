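test_that("findSSRs detects planted repeats under the unit-length minima", {
  # (GAA)x10 flanked by neutral sequence: one tri-nucleotide locus
  s <- c(t1 = paste0("ACGTC", strrep("GAA", 10), "TTCCA"))
  loci <- findSSRs(s)
  expect_equal(length(loci), 1L)
  expect_equal(S4Vectors::mcols(loci)$motif, "GAA")
  expect_equal(S4Vectors::mcols(loci)$repeatCount, 10L)
  expect_equal(GenomicRanges::start(loci), 6L)
  expect_equal(GenomicRanges::end(loci), 35L)
  expect_equal(S4Vectors::mcols(loci)$motifClass, "AAG/CTT")

  # (TCA)x6 meets the tri minimum of 5
  loci <- findSSRs(c(t1 = paste0("GGCCG", strrep("TCA", 6), "GGTTG")))
  expect_equal(S4Vectors::mcols(loci)$repeatCount, 6L)

  # (AT)x5 is below the di minimum of 6
  expect_length(findSSRs(c(t1 = paste0("CCGCG", strrep("AT", 5), "GCGCC"))),
                0L)
  # mononucleotide runs are excluded entirely
  expect_length(findSSRs(c(t1 = strrep("A", 30))), 0L)
  # empty sequence is fine, non-nucleotide characters are not
  expect_length(findSSRs(c(t1 = "")), 0L)
  expect_error(findSSRs(c(t1 = "ACGTX")), "non-nucleotide")
})

test_that("N terminates a repeat run", {
  s <- c(t1 = paste0("CCG", strrep("GAA", 4), "N", strrep("GAA", 4), "TTC"))
  expect_length(findSSRs(s), 0L)   # two 4-unit halves, both below minimum
  s2 <- c(t1 = paste0("CCG", strrep("GAA", 6), "N", strrep("GAA", 4), "TTC"))
  loci <- findSSRs(s2)
  expect_equal(S4Vectors::mcols(loci)$repeatCount, 6L)
})

test_that("reported runs are maximal and the count is the full run", {
  # 13 copies with an extendable-looking flank: A then (AG)x7 reads (GA)
  # phase too; whatever phase is reported must cover the whole run
  s <- c(t1 = paste0("CCTT", "A", strrep("AG", 7), "CCGG"))
  loci <- findSSRs(s)
  expect_equal(length(loci), 1L)
  expect_equal(S4Vectors::mcols(loci)$repeatCount, 7L)
  seq <- "CCTTAAGAGAGAGAGAGAGCCGG"
  st <- GenomicRanges::start(loci); en <- GenomicRanges::end(loci)
  motif <- S4Vectors::mcols(loci)$motif
  p <- nchar(motif)
  expect_equal(substr(seq, st, en),
               strrep(motif, S4Vectors::mcols(loci)$repeatCount))
  # not extendable by one unit either side
  expect_false(substr(seq, st - p, st - 1) == motif)
  expect_false(substr(seq, en + 1, en + p) == motif)
})

test_that("canonical classes are closed under rotation and complement", {
  expect_equal(canonicalClass("TTC"), "AAG/CTT")
  expect_equal(canonicalClass("GAA"), "AAG/CTT")
  expect_equal(canonicalClass("AG"), canonicalClass("CT"))
  expect_equal(canonicalClass("AG"), canonicalClass("GA"))
  expect_error(canonicalClass("ATAT"), "reducible")
  expect_error(canonicalClass("A"), "length")
  # class closure over many random primitive motifs
  set.seed(42)
  for (i in 1:200) {
    p <- sample(2:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
               collapse = "")
    prim <- tryCatch({ canonicalClass(m); TRUE },
                     error = function(e) FALSE)
    if (!prim) next
    lab <- canonicalClass(m)
    rot <- paste0(substr(m, 2, p), substr(m, 1, 1))
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1]]),
                collapse = "")
    expect_equal(canonicalClass(rot), lab)
    expect_equal(canonicalClass(rc), lab)
  }
})

test_that("mined loci keep their canonical class when the transcript is
           reverse-complemented", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste0(randomSequence(60), strrep("CTG", 7), randomSequence(60))
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    fwd <- findSSRs(c(t = s)); rev <- findSSRs(c(t = rc))
    expect_equal(length(fwd), length(rev))
    expect_setequal(S4Vectors::mcols(fwd)$motifClass,
                    S4Vectors::mcols(rev)$motifClass)
    # coordinates mirror up to the repeat phase: with a partial trailing
    # unit of r bases (r < unit length), the leftmost-placement convention
    # shifts the mirrored start by r
    L <- nchar(s)
    fo <- order(GenomicRanges::start(fwd))
    ro <- order(-GenomicRanges::end(rev))
    mirroredStart <- (L - GenomicRanges::end(rev) + 1)[ro]
    unit <- nchar(S4Vectors::mcols(fwd)$motif)[fo]
    expect_true(all(abs(GenomicRanges::start(fwd)[fo] - mirroredStart) <
                      unit))
    expect_equal(S4Vectors::mcols(fwd)$repeatCount[fo],
                 S4Vectors::mcols(rev)$repeatCount[ro])
  }
})

test_that("summarizeSSRs reproduces printed composition shares and density", {
  # worked example with the published category counts: 490 di, 646 tri,
  # 485 longer units over a 40178 x 446 bp transcriptome
  loci <- GenomicRanges::GRanges(
    rep("t", 1621), IRanges::IRanges(seq_len(1621) * 50,
                                     width = c(rep(12, 490), rep(15, 646),
                                               rep(16, 485))))
  S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
    motif = c(rep("AG", 490), rep("GAA", 646), rep("ATCG", 485)),
    motifClass = "x", repeatCount = 1L, region = "UNCLASSIFIED")
  sm <- summarizeSSRs(loci, totalBp = 40178 * 446)
  expect_equal(unname(sm$shares$byUnitLength[["3"]]), 39.9)
  expect_equal(unname(sm$shares$byUnitLength[["2"]]), 30.2)
  expect_equal(unname(sm$shares$byUnitLength[["2"]] +
                        sm$shares$byUnitLength[["3"]]), 70.1)
  expect_equal(sm$densityKbPerSSR, 11.1)
  expect_equal(sum(sm$byUnitLength), sm$totalLoci)
  expect_equal(sum(sm$byClass), sm$totalLoci)
  expect_equal(sum(sm$byRegion), sm$totalLoci)
})

test_that("summarizeSSRs handles the degenerate cases", {
  gr <- GenomicRanges::GRanges("t", IRanges::IRanges(100, 111))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    motif = "AG", motifClass = "AG/CT", repeatCount = 6L,
    region = "UNCLASSIFIED")
  expect_equal(summarizeSSRs(gr, 10000)$densityKbPerSSR, 10.0)
  empty <- findSSRs(c(t = "ACGTACT"))
  sm0 <- summarizeSSRs(empty, 10000)
  expect_equal(sm0$totalLoci, 0L)
  expect_true(is.na(sm0$densityKbPerSSR))
  expect_output(print(sm0), "undefined")
})

test_that("checkFlanks matches an exhaustive designability oracle", {
  # spec'd quick cases
  s <- randomSequence(1000)
  near5 <- list(start = 11, end = 40)
  expect_false(checkFlanks(s, near5, minFlank = 50)$designable)
  centred <- list(start = 480, end = 510)
  expect_true(checkFlanks(s, centred, minFlank = 50)$designable)
  # oracle: enumerate every product placement
  oracle <- function(L, st, en, minFlank, pr) {
    for (a in seq_len(st - minFlank)) {
      if (st - a < minFlank) next
      for (b in en:(L)) {
        if (b - en < minFlank) next
        len <- b - a + 1
        if (len >= pr[1] && len <= pr[2]) return(TRUE)
      }
    }
    FALSE
  }
  set.seed(11)
  for (i in 1:50) {
    L <- sample(120:400, 1)
    st <- sample(seq_len(L - 30), 1); en <- min(L, st + sample(10:25, 1))
    got <- checkFlanks(randomSequence(L), list(start = st, end = en),
                       minFlank = 30, productRange = c(80, 200))$designable
    want <- st > 30 && L - en >= 30 && oracle(L, st, en, 30, c(80, 200))
    expect_identical(got, want)
  }
})

test_that("locus tables and primer-design input round-trip", {
  s <- c(tA = paste0(randomSequence(200), strrep("GAA", 8),
                     randomSequence(200)))
  loci <- findSSRs(s)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSsrTable(loci, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$start1, GenomicRanges::start(loci))
  expect_equal(back$motif, S4Vectors::mcols(loci)$motif)
  b <- withr::local_tempfile(fileext = ".boulder")
  n <- writePrimerInput(s, loci, b)
  expect_equal(n, 1L)
  expect_true(any(grepl("^SEQUENCE_TARGET=", readLines(b))))
})
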