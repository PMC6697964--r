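#' Longest ATG-initiated open reading frame
#'
#' Scans the three forward frames of a transcript and the three frames of its
#' reverse complement for ATG..in-frame-stop spans (stop codon included) and
#' returns the longest one at least `minLenNt` long. Ties are broken in favour
#' of the forward orientation, then the smallest start coordinate on the given
#' sequence. Candidates running off the 3' end without a stop codon are
#' rejected unless `requireStop = FALSE`, in which case they are accepted with
#' the transcript end as their boundary (truncated to a codon multiple).
#'
#' @param sequence a single nucleotide sequence (character or `DNAString`).
#' @param minLenNt minimum ORF length in nucleotides (default 90 = 30 codons).
#' @param requireStop logical; reject stop-less candidates (default TRUE).
#' @return A list with `start`, `end` (1-based inclusive on the input
#'   sequence), `orientation` (`"FORWARD"`/`"REVERSE"`) and `lengthNt`, or
#'   `NULL` when no ORF qualifies.
#' @export
findLongestOrf <- function(sequence, minLenNt = 90L, requireStop = TRUE) {
  seq <- asSequenceCharacters(sequence)[[1]]
  assertNucleotide(seq, allowN = TRUE)
  L <- nchar(seq)
  if (L < minLenNt) return(NULL)
  best <- NULL
  consider <- function(start, end, orientation) {
    lengthNt <- end - start + 1L
    cand <- list(start = start, end = end, orientation = orientation,
                 lengthNt = lengthNt)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    if (lengthNt > best$lengthNt) { best <<- cand; return(invisible()) }
    if (lengthNt == best$lengthNt) {
      if (best$orientation == "REVERSE" && orientation == "FORWARD") {
        best <<- cand
      } else if (best$orientation == orientation && start < best$start) {
        best <<- cand
      }
    }
    invisible()
  }
  scanStrand <- function(s, orientation) {
    n <- nchar(s)
    for (frame in 0:2) {
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      atg <- which(codons == "ATG")
      if (length(atg) == 0L) next
      stops <- which(codons %in% STOP_CODONS)
      for (a in atg) {
        nxt <- stops[stops >= a]
        if (length(nxt) > 0L) {
          e <- starts[nxt[1]] + 2L
        } else if (!requireStop) {
          lastFull <- starts[length(starts)] + 2L
          e <- lastFull
        } else next
        st <- starts[a]
        if (e - st + 1L < minLenNt) next
        if (orientation == "FORWARD") {
          consider(st, e, "FORWARD")
        } else {
          consider(L - e + 1L, L - st + 1L, "REVERSE")
        }
      }
    }
  }
  scanStrand(seq, "FORWARD")
  scanStrand(reverseComplement1(seq), "REVERSE")
  best
}

#' Annotate the longest ORF of every transcript
#'
#' @param x `DNAStringSet` or named character vector of transcripts.
#' @inheritParams findLongestOrf
#' @return A `GRanges` (1-based inclusive, strand `+` for FORWARD, `-` for
#'   REVERSE) with one row per transcript that has an accepted ORF; metadata
#'   column `lengthNt`. Transcripts without an ORF are absent.
#' @export
annotateOrfs <- function(x, minLenNt = 90L, requireStop = TRUE) {
  seqs <- asSequenceCharacters(x)
  anns <- lapply(names(seqs), function(id) {
    orf <- findLongestOrf(seqs[[id]], minLenNt, requireStop)
    if (is.null(orf)) return(NULL)
    data.frame(transcriptId = id, start = orf$start, end = orf$end,
               strand = if (orf$orientation == "FORWARD") "+" else "-",
               lengthNt = orf$lengthNt)
  })
  anns <- do.call(rbind, anns)
  if (is.null(anns)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(lengthNt = integer(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = anns$transcriptId,
    ranges = IRanges::IRanges(anns$start, anns$end),
    strand = anns$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(lengthNt = anns$lengthNt)
  gr
}

#' Classify a feature interval relative to an ORF
#'
#' Orientation-aware UTR/CDS assignment: a feature entirely on the 5' side of
#' the CDS (in ORF orientation) is `FIVE_UTR`, entirely on the 3' side is
#' `THREE_UTR`, and any overlap with the CDS makes it `CDS`. Transcripts
#' without an accepted ORF give `UNCLASSIFIED`.
#'
#' @param orf `NULL`, or a list from [findLongestOrf()], or a one-row
#'   `GRanges` from [annotateOrfs()].
#' @param start,end feature interval, 1-based inclusive.
#' @return One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"UNCLASSIFIED"`.
#' @export
classifyRegion <- function(orf, start, end) {
  if (start > end) stop("inverted feature interval")
  if (is.null(orf) || (is(orf, "GRanges") && length(orf) == 0L))
    return("UNCLASSIFIED")
  if (is(orf, "GRanges")) {
    cdsStart <- GenomicRanges::start(orf)[1]
    cdsEnd <- GenomicRanges::end(orf)[1]
    forward <- as.character(GenomicRanges::strand(orf))[1] != "-"
  } else {
    cdsStart <- orf$start
    cdsEnd <- orf$end
    forward <- orf$orientation == "FORWARD"
  }
  if (end < cdsStart) return(if (forward) "FIVE_UTR" else "THREE_UTR")
  if (start > cdsEnd) return(if (forward) "THREE_UTR" else "FIVE_UTR")
  "CDS"
}

#' Region-classify a set of feature ranges
#'
#' @param features `GRanges` of features (e.g. SSR loci or SNP positions).
#' @param orfs `GRanges` from [annotateOrfs()].
#' @return `features` with its `region` metadata column filled in.
#' @export
classifyFeatureRegions <- function(features, orfs) {
  orfIds <- as.character(GenomicRanges::seqnames(orfs))
  region <- vapply(seq_along(features), function(i) {
    id <- as.character(GenomicRanges::seqnames(features))[i]
    j <- match(id, orfIds)
    orf <- if (is.na(j)) NULL else orfs[j]
    classifyRegion(orf, GenomicRanges::start(features)[i],
                   GenomicRanges::end(features)[i])
  }, character(1))
  S4Vectors::mcols(features)$region <- region
  features
}

#' Write an ORF annotation table
#'
#' @param orfs `GRanges` from [annotateOrfs()].
#' @param path output TSV path (1-based inclusive coordinates).
#' @return The path, invisibly.
#' @export
writeOrfTable <- function(orfs, path) {
  df <- data.frame(
    transcript = as.character(GenomicRanges::seqnames(orfs)),
    cds_start1 = GenomicRanges::start(orfs),
    cds_end1 = GenomicRanges::end(orfs),
    orientation = ifelse(as.character(GenomicRanges::strand(orfs)) == "-",
                         "REVERSE", "FORWARD"),
    length_nt = S4Vectors::mcols(orfs)$lengthNt)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
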