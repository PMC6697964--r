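#' SSR search criteria
#'
#' Unit-length-specific minimum contiguous repeat counts for perfect SSR
#' mining. The defaults require at least 6, 5, 4, 4 and 3 contiguous units for
#' di-, tri-, tetra-, penta- and hexa-nucleotide motifs respectively;
#' mononucleotide runs are excluded from the search.
#'
#' @param minRepeats named integer vector, names "2".."6" (unit length in bp),
#'   values the minimum number of contiguous repeat units.
#' @param includeMono logical; when TRUE a "1" entry may be supplied and
#'   mononucleotide runs are mined too. Off by default.
#' @return An object of class `SSRCriteria` (a validated list).
#' @export
ssrCriteria <- function(minRepeats = c("2" = 6L, "3" = 5L, "4" = 4L,
                                       "5" = 4L, "6" = 3L),
                        includeMono = FALSE) {
  minRepeats <- setNames(as.integer(minRepeats), names(minRepeats))
  wanted <- if (includeMono) as.character(1:6) else as.character(2:6)
  if (!setequal(names(minRepeats), wanted)) {
    stop("minRepeats must have keys exactly {", paste(wanted, collapse = ","),
         "}")
  }
  if (any(minRepeats < 2L)) stop("minimum repeat counts must be >= 2")
  structure(list(minRepeats = minRepeats, includeMono = includeMono),
            class = "SSRCriteria")
}

#' Mine perfect SSRs from nucleotide sequences
#'
#' Detects every maximal perfect tandem repeat whose unit length is covered by
#' `criteria` and whose contiguous repeat count meets the unit-length-specific
#' minimum. Motifs must be irreducible (not a power of a shorter unit); any
#' non-ACGT base terminates a run. Runs are reported left-to-right and each
#' position is assigned to at most one locus: when candidate runs overlap the
#' longest run (in bp) wins, with ties resolved in favour of the smaller unit
#' length and then the leftmost start.
#'
#' @param x a `DNAStringSet`, `DNAString`, or named character vector of
#'   nucleotide sequences (A/C/G/T/N).
#' @param criteria an [ssrCriteria()] object.
#' @return A `GRanges` (1-based, inclusive) with one row per SSR locus and
#'   metadata columns `motif`, `motifClass` (canonical label), `repeatCount`
#'   and `region` (initialised to `"UNCLASSIFIED"`).
#' @examples
#' findSSRs(c(t1 = paste0("ACGTT", strrep("GAA", 10), "CCTGA")))
#' @export
findSSRs <- function(x, criteria = ssrCriteria()) {
  seqs <- asSequenceCharacters(x)
  assertNucleotide(seqs, allowN = TRUE)
  rows <- lapply(names(seqs), function(id) {
    cand <- ssrCandidates(seqs[[id]], criteria)
    if (nrow(cand) == 0L) return(cand)
    cand$transcriptId <- id
    resolveOverlaps(cand)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      motif = character(0), motifClass = character(0),
      repeatCount = integer(0), region = character(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$transcriptId,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    motif = rows$motif,
    motifClass = vapply(rows$motif, canonicalClass, character(1),
                        USE.NAMES = FALSE),
    repeatCount = rows$count,
    region = rep("UNCLASSIFIED", nrow(rows)))
  gr
}

## Candidate maximal runs for every unit length, before overlap resolution.
## Perl backreference patterns find maximal perfect tandem repeats greedily
## and left-to-right, which yields the leftmost phase of each periodic region.
ssrCandidates <- function(seq, criteria) {
  out <- list()
  for (pChr in names(criteria$minRepeats)) {
    p <- as.integer(pChr)
    minRep <- criteria$minRepeats[[pChr]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, minRep - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    motifs <- substring(seq, starts, starts + p - 1L)
    keep <- vapply(motifs, isPrimitiveMotif, logical(1), USE.NAMES = FALSE)
    if (!any(keep)) next
    out[[pChr]] <- data.frame(
      start = starts[keep],
      end = starts[keep] + lens[keep] - 1L,
      motif = motifs[keep],
      unit = p,
      count = lens[keep] %/% p,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## Longest run wins; ties to smaller unit length, then leftmost start.
resolveOverlaps <- function(cand) {
  width <- cand$end - cand$start + 1L
  ord <- order(-width, cand$unit, cand$start)
  cand <- cand[ord, , drop = FALSE]
  taken <- IRanges::IRanges()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ir <- IRanges::IRanges(cand$start[i], cand$end[i])
    if (length(IRanges::findOverlaps(ir, taken)) == 0L) {
      keep[i] <- TRUE
      taken <- c(taken, ir)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Canonical motif class label
#'
#' Maps a repeat unit to its complement/rotation equivalence class. The class
#' representative `M` is the lexicographically smallest string among all
#' cyclic rotations of the motif and of its reverse complement; the label is
#' `"M/revcomp(M)"`, so e.g. `"TTC"`, `"GAA"` and `"AGA"` all map to
#' `"AAG/CTT"`.
#'
#' @param motif repeat unit of length 2-6; must be irreducible.
#' @return A single character label.
#' @export
canonicalClass <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 2L || nchar(motif) > 6L)
    stop("motif length must be 2-6")
  assertNucleotide(motif, allowN = FALSE)
  if (!isPrimitiveMotif(motif))
    stop("motif '", motif, "' is reducible (a power of a shorter unit)")
  rot <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n) - 1L, function(k) {
      paste0(substr(s, k + 1L, n), substr(s, 1L, k))
    }, character(1))
  }
  m <- min(c(rot(motif), rot(reverseComplement1(motif))))
  paste0(m, "/", reverseComplement1(m))
}

#' Summarize a set of mined SSR loci
#'
#' Tallies loci by unit length, canonical class and region, counts the
#' transcripts carrying at least one SSR, and reports the SSR density as
#' kilobases of surveyed sequence per SSR locus.
#'
#' @param loci `GRanges` from [findSSRs()] (optionally region-classified).
#' @param totalBp total surveyed sequence length in bp (must be > 0).
#' @return An `SSRSummary` list: `totalLoci`, `byUnitLength`, `byClass`,
#'   `byRegion`, `transcriptsWithSSR`, `densityKbPerSSR` (NA when no loci),
#'   and `shares` (percentages of `totalLoci`, one decimal).
#' @export
summarizeSSRs <- function(loci, totalBp) {
  stopifnot(is(loci, "GRanges"), totalBp > 0)
  n <- length(loci)
  if (n == 0L) {
    return(structure(list(
      totalLoci = 0L, byUnitLength = integer(0), byClass = integer(0),
      byRegion = integer(0), transcriptsWithSSR = 0L,
      densityKbPerSSR = NA_real_, shares = list()), class = "SSRSummary"))
  }
  unit <- nchar(S4Vectors::mcols(loci)$motif)
  byUnit <- table(factor(unit, levels = sort(unique(unit))))
  byClass <- sort(table(S4Vectors::mcols(loci)$motifClass), decreasing = TRUE)
  byRegion <- table(S4Vectors::mcols(loci)$region)
  pct <- function(tab) round(100 * as.numeric(tab) / n, 1)
  structure(list(
    totalLoci = n,
    byUnitLength = as.integer(byUnit) |> setNames(names(byUnit)),
    byClass = as.integer(byClass) |> setNames(names(byClass)),
    byRegion = as.integer(byRegion) |> setNames(names(byRegion)),
    transcriptsWithSSR = length(unique(as.character(
      GenomicRanges::seqnames(loci)))),
    densityKbPerSSR = round((totalBp / 1000) / n, 1),
    shares = list(
      byUnitLength = setNames(pct(byUnit), names(byUnit)),
      byClass = setNames(pct(byClass), names(byClass)),
      byRegion = setNames(pct(byRegion), names(byRegion)))),
    class = "SSRSummary")
}

#' @export
print.SSRSummary <- function(x, ...) {
  cat("SSR summary:", x$totalLoci, "loci in", x$transcriptsWithSSR,
      "transcript(s)\n")
  if (x$totalLoci == 0L) {
    cat("  density: undefined (no loci)\n")
    return(invisible(x))
  }
  cat("  density: one SSR per", x$densityKbPerSSR, "kb\n")
  cat("  by unit length (%):",
      paste0(names(x$byUnitLength), "=", x$byUnitLength, " (",
             x$shares$byUnitLength, "%)", collapse = ", "), "\n")
  top <- utils::head(x$byClass, 3)
  cat("  top motif classes:",
      paste0(names(top), "=", top, collapse = ", "), "\n")
  invisible(x)
}

#' Primer-design flank adequacy for an SSR locus
#'
#' A locus is designable when both flanks are at least `minFlank` bp long and
#' some amplicon within `productRange` can contain flank + locus + flank.
#'
#' @param transcript a single sequence (character or `DNAString`).
#' @param locus one-row `GRanges` (or list with `start`, `end`, 1-based
#'   inclusive).
#' @param minFlank minimum flank length in bp (default 50).
#' @param productRange allowed PCR product size range in bp.
#' @return A list: `designable`, `leftFlank`, `rightFlank` (sequences),
#'   `leftLen`, `rightLen`, `reason` (NA when designable).
#' @export
checkFlanks <- function(transcript, locus, minFlank = 50L,
                        productRange = c(100L, 250L)) {
  seq <- asSequenceCharacters(transcript)[[1]]
  if (is(locus, "GRanges")) {
    st <- GenomicRanges::start(locus)[1]; en <- GenomicRanges::end(locus)[1]
  } else {
    st <- locus$start; en <- locus$end
  }
  L <- nchar(seq)
  if (st < 1L || en > L || st > en) stop("locus not within transcript")
  leftLen <- st - 1L
  rightLen <- L - en
  width <- en - st + 1L
  reason <- NA_character_
  if (leftLen < minFlank || rightLen < minFlank) {
    reason <- "flank-too-short"
  } else if (width + 2L * minFlank > productRange[2]) {
    reason <- "product-too-large"
  } else if (width + leftLen + rightLen < productRange[1]) {
    reason <- "product-too-small"
  }
  list(designable = is.na(reason),
       leftFlank = substr(seq, 1L, leftLen),
       rightFlank = substr(seq, en + 1L, L),
       leftLen = leftLen, rightLen = rightLen, reason = reason)
}

#' Write an SSR locus table
#'
#' Writes one row per locus with 1-based inclusive coordinates.
#'
#' @param loci `GRanges` from [findSSRs()].
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeSsrTable <- function(loci, path) {
  df <- data.frame(
    transcript = as.character(GenomicRanges::seqnames(loci)),
    start1 = GenomicRanges::start(loci),
    end1 = GenomicRanges::end(loci),
    motif = S4Vectors::mcols(loci)$motif,
    class = S4Vectors::mcols(loci)$motifClass,
    count = S4Vectors::mcols(loci)$repeatCount,
    region = S4Vectors::mcols(loci)$region)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export primer-design input in Boulder-IO tag format
#'
#' Emits one Boulder-IO record per designable locus, with the repeat marked
#' as the primer target, for downstream primer-design tools.
#'
#' @param transcripts named sequences containing the loci.
#' @param loci `GRanges` from [findSSRs()].
#' @param path output path.
#' @param minFlank,productRange passed to [checkFlanks()].
#' @return Number of records written, invisibly.
#' @export
writePrimerInput <- function(transcripts, loci, path, minFlank = 50L,
                             productRange = c(100L, 250L)) {
  seqs <- asSequenceCharacters(transcripts)
  con <- file(path, "w")
  on.exit(close(con))
  nOut <- 0L
  for (i in seq_along(loci)) {
    id <- as.character(GenomicRanges::seqnames(loci))[i]
    rep <- checkFlanks(seqs[[id]], loci[i], minFlank, productRange)
    if (!rep$designable) next
    st <- GenomicRanges::start(loci)[i]
    wd <- GenomicRanges::width(loci)[i]
    writeLines(c(
      sprintf("SEQUENCE_ID=%s_ssr%d", id, i),
      sprintf("SEQUENCE_TEMPLATE=%s", seqs[[id]]),
      sprintf("SEQUENCE_TARGET=%d,%d", st, wd),
      sprintf("PRIMER_PRODUCT_SIZE_RANGE=%d-%d", productRange[1],
              productRange[2]),
      "="), con)
    nOut <- nOut + 1L
  }
  invisible(nOut)
}
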