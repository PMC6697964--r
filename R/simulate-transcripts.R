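#' Generate synthetic transcript contigs with planted ORFs
#'
#' Emulates a de novo transcriptome assembly: contig lengths are drawn from a
#' right-skewed (truncated lognormal) distribution within `lengthRange`, and a
#' fraction of transcripts carries a single dominant forward-strand
#' ATG-initiated ORF of at least 300 nt flanked by UTRs. Each ORF-bearing
#' transcript is verified (and resampled if necessary) so that the planted
#' span is exactly the longest six-frame ATG ORF of the sequence, which makes
#' the returned truth table exact for downstream recovery scoring.
#'
#' @param nTranscripts number of contigs.
#' @param lengthRange contig length range in bp (min >= 200).
#' @param gcFraction GC content of the background base distribution.
#' @param orfFraction fraction of transcripts given a planted ORF.
#' @param seed integer seed; equal seeds give bit-identical output.
#' @return A list: `transcripts` (`DNAStringSet`, names `TC00001`, ...) and
#'   `orfTruth` (data.frame `transcriptId`, `cdsStart`, `cdsEnd`,
#'   `orientation`, `lengthNt`; 1-based inclusive).
#' @export
generateTranscripts <- function(nTranscripts, lengthRange = c(280L, 6445L),
                                gcFraction = 0.45, orfFraction = 0.964,
                                seed = 1L) {
  stopifnot(nTranscripts >= 1, gcFraction >= 0, gcFraction <= 1,
            orfFraction >= 0, orfFraction <= 1)
  if (lengthRange[1] > lengthRange[2]) stop("degenerate lengthRange")
  if (lengthRange[1] < 200L) stop("lengthRange minimum must be >= 200")
  withSeed(seedFor(seed, "generate_transcripts"), {
    ids <- sprintf("TC%05d", seq_len(nTranscripts))
    lens <- drawLengths(nTranscripts, lengthRange)
    nOrf <- round(orfFraction * nTranscripts)
    ## ORFs need >= 300 nt CDS plus short UTRs; prefer the longest contigs
    eligible <- which(lens >= 330L)
    if (length(eligible) < nOrf) {
      lens[order(lens)[seq_len(nOrf - length(eligible))]] <- 330L +
        as.integer(runif(nOrf - length(eligible), 0, 200))
      eligible <- which(lens >= 330L)
    }
    orfIdx <- sort(sample(eligible, nOrf))
    seqs <- character(nTranscripts)
    truth <- vector("list", nTranscripts)
    for (i in seq_len(nTranscripts)) {
      if (i %in% orfIdx) {
        r <- makeOrfTranscript(lens[i], gcFraction)
        seqs[i] <- r$seq
        truth[[i]] <- data.frame(transcriptId = ids[i], cdsStart = r$start,
                                 cdsEnd = r$end, orientation = "FORWARD",
                                 lengthNt = r$end - r$start + 1L)
      } else {
        seqs[i] <- makeOrfFreeTranscript(lens[i], gcFraction)
      }
    }
    transcripts <- Biostrings::DNAStringSet(setNames(seqs, ids))
    orfTruth <- do.call(rbind, truth)
    if (is.null(orfTruth)) {
      orfTruth <- data.frame(transcriptId = character(0),
                             cdsStart = integer(0), cdsEnd = integer(0),
                             orientation = character(0), lengthNt = integer(0))
    }
    list(transcripts = transcripts, orfTruth = orfTruth)
  })
}

drawLengths <- function(n, lengthRange) {
  lens <- integer(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- as.integer(round(exp(rnorm(length(todo), log(390), 0.45))))
    ok <- draw >= lengthRange[1] & draw <= lengthRange[2]
    lens[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  lens
}

## One transcript with a planted forward ORF that is verifiably the longest
## six-frame ATG ORF. Rejection sampling: the acceptance check runs the same
## ORF finder the analysis uses, so the truth table is exact by construction.
makeOrfTranscript <- function(len, gcFraction, maxTries = 200L) {
  for (try in seq_len(maxTries)) {
    maxCodons <- (len - 24L) %/% 3L
    capCodons <- max(100L, as.integer(0.8 * len) %/% 3L)
    hiCodons <- max(100L, min(maxCodons, capCodons))
    nCod <- if (hiCodons <= 100L) 100L else
      100L + sample.int(hiCodons - 100L + 1L, 1L) - 1L
    cdsLen <- 3L * nCod
    utr5 <- 3L + sample.int(len - cdsLen - 5L, 1L) - 1L
    utr3 <- len - cdsLen - utr5
    nCodons <- cdsLen %/% 3L - 2L
    codons <- replicate(nCodons,
                        paste(randomBases(3, gcFraction), collapse = ""))
    bad <- codons %in% STOP_CODONS
    while (any(bad)) {
      codons[bad] <- replicate(sum(bad),
                               paste(randomBases(3, gcFraction),
                                     collapse = ""))
      bad <- codons %in% STOP_CODONS
    }
    cds <- paste0("ATG", paste(codons, collapse = ""),
                  sample(STOP_CODONS, 1))
    seq <- paste0(paste(randomBases(utr5, gcFraction), collapse = ""), cds,
                  paste(randomBases(utr3, gcFraction), collapse = ""))
    orf <- findLongestOrf(seq, minLenNt = 90L)
    if (!is.null(orf) && orf$orientation == "FORWARD" &&
        orf$start == utr5 + 1L && orf$end == utr5 + cdsLen) {
      return(list(seq = seq, start = utr5 + 1L, end = utr5 + cdsLen))
    }
  }
  stop("could not construct a transcript with a dominant planted ORF")
}

makeOrfFreeTranscript <- function(len, gcFraction, maxTries = 200L) {
  for (try in seq_len(maxTries)) {
    seq <- paste(randomBases(len, gcFraction), collapse = "")
    if (is.null(findLongestOrf(seq, minLenNt = 90L))) return(seq)
  }
  stop("could not construct an ORF-free transcript")
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param transcripts `DNAStringSet` or named character vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeFasta <- function(transcripts, path) {
  x <- if (is(transcripts, "DNAStringSet")) transcripts
       else Biostrings::DNAStringSet(asSequenceCharacters(transcripts))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Plant perfect SSRs into transcripts
#'
#' Replaces a same-length window of each chosen transcript with a perfect
#' tandem repeat, with flanking guard bases chosen so the planted run is
#' maximal (not extendable by one unit in either direction). Planted loci
#' never overlap; region placement is relative to the transcript's planted
#' ORF. Background SSRs meeting the mining criteria are first disrupted by a
#' single point substitution so recovery scoring against the returned truth
#' can demand exact precision. Every edit is verified to leave the planted
#' ORF annotation unchanged (edits are re-drawn otherwise).
#'
#' @param transcripts `DNAStringSet` from [generateTranscripts()].
#' @param orfTruth its ORF truth table.
#' @param motifMix named integer vector: motif (e.g. `"AAG"`) -> number of
#'   loci to plant.
#' @param regionMix named numeric vector over `FIVE_UTR`, `CDS`, `THREE_UTR`
#'   giving placement fractions (normalised internally).
#' @param repeatRange extra repeat units above the mining minimum to draw
#'   from, `count ~ min + U{0..repeatRange}`.
#' @param criteria [ssrCriteria()] the downstream miner will use.
#' @param seed integer seed.
#' @return A list: `transcripts` (modified `DNAStringSet`) and `ssrTruth`
#'   (data.frame `transcriptId`, `start`, `end` (1-based inclusive), `motif`,
#'   `motifClass`, `repeatCount`, `region`).
#' @export
plantSSRs <- function(transcripts, orfTruth, motifMix,
                      regionMix = c(FIVE_UTR = 0.19, CDS = 0.60,
                                    THREE_UTR = 0.21),
                      repeatRange = 6L, criteria = ssrCriteria(), seed = 1L) {
  stopifnot(length(motifMix) > 0, all(motifMix >= 0))
  regionMix <- regionMix[regionMix > 0]
  if (!all(names(regionMix) %in% c("FIVE_UTR", "CDS", "THREE_UTR")))
    stop("regionMix names must be FIVE_UTR/CDS/THREE_UTR")
  if (any(names(regionMix) %in% c("FIVE_UTR", "CDS", "THREE_UTR")) &&
      nrow(orfTruth) == 0L)
    stop("region placement requested but no transcript has an ORF")
  withSeed(seedFor(seed, "plant_ssrs"), {
    seqs <- asSequenceCharacters(transcripts)
    seqs <- disruptBackgroundSSRs(seqs, orfTruth, criteria)
    regionMix <- regionMix / sum(regionMix)
    plan <- rep(names(motifMix), times = as.integer(motifMix))
    regions <- sample(names(regionMix), length(plan), replace = TRUE,
                      prob = regionMix)
    occupied <- list()   # per transcript: IRanges of planted loci
    truth <- vector("list", length(plan))
    orfIds <- orfTruth$transcriptId
    for (k in seq_along(plan)) {
      motif <- plan[k]
      p <- nchar(motif)
      if (!isPrimitiveMotif(motif)) stop("motif '", motif, "' is reducible")
      minRep <- criteria$minRepeats[[as.character(p)]]
      placed <- FALSE
      for (attempt in seq_len(400L)) {
        count <- minRep + sample.int(repeatRange + 1L, 1L) - 1L
        insLen <- p * count + 2L          # repeat plus two guard bases
        tid <- sample(orfIds, 1L)
        orf <- orfTruth[orfTruth$transcriptId == tid, ]
        win <- regionWindow(regions[k], orf, nchar(seqs[[tid]]), insLen)
        if (is.null(win)) next
        st <- win[1] + sample.int(win[2] - win[1] - insLen + 2L, 1L) - 1L
        ir <- IRanges::IRanges(st, st + insLen - 1L)
        occ <- occupied[[tid]]
        if (!is.null(occ) &&
            length(IRanges::findOverlaps(ir, occ)) > 0L) next
        guardL <- sample(setdiff(BASES, substr(motif, p, p)), 1L)
        guardR <- sample(setdiff(BASES, substr(motif, 1L, 1L)), 1L)
        insert <- paste0(guardL, strrep(motif, count), guardR)
        newSeq <- paste0(substr(seqs[[tid]], 1L, st - 1L), insert,
                         substr(seqs[[tid]], st + insLen, nchar(seqs[[tid]])))
        if (!orfPreserved(newSeq, orf)) next
        locusStart <- st + 1L
        locusEnd <- st + insLen - 2L
        if (classifyRegion(list(start = orf$cdsStart, end = orf$cdsEnd,
                                orientation = orf$orientation),
                           locusStart, locusEnd) != regions[k]) next
        ## the edit must create exactly this locus and no other
        mined <- findSSRs(setNames(newSeq, tid), criteria)
        expect <- c(occupiedLoci(truth, tid),
                    list(c(locusStart, locusEnd)))
        if (!minedMatches(mined, expect)) next
        seqs[[tid]] <- newSeq
        occupied[[tid]] <- c(if (is.null(occ)) IRanges::IRanges() else occ,
                             IRanges::IRanges(st, st + insLen - 1L))
        truth[[k]] <- data.frame(
          transcriptId = tid, start = locusStart, end = locusEnd,
          motif = motif, motifClass = canonicalClass(motif),
          repeatCount = count, region = regions[k])
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place an SSR locus for motif '", motif,
             "' in region ", regions[k])
    }
    list(transcripts = Biostrings::DNAStringSet(seqs),
         ssrTruth = do.call(rbind, truth))
  })
}

occupiedLoci <- function(truth, tid) {
  done <- Filter(function(d) !is.null(d) && d$transcriptId == tid, truth)
  lapply(done, function(d) c(d$start, d$end))
}

minedMatches <- function(mined, expect) {
  if (length(mined) != length(expect)) return(FALSE)
  got <- cbind(GenomicRanges::start(mined), GenomicRanges::end(mined))
  want <- do.call(rbind, expect)
  ord1 <- order(got[, 1]); ord2 <- order(want[, 1])
  all(got[ord1, , drop = FALSE] == want[ord2, , drop = FALSE])
}

## Window (1-based [from, to]) of positions an insert of length insLen may
## occupy inside the requested region, keeping 2 bp off region boundaries and
## never touching the start/stop codons.
regionWindow <- function(region, orf, len, insLen) {
  lims <- switch(region,
    FIVE_UTR = c(2L, orf$cdsStart - 2L),
    CDS = c(orf$cdsStart + 4L, orf$cdsEnd - 4L),
    THREE_UTR = c(orf$cdsEnd + 2L, len - 1L))
  if (lims[2] - lims[1] + 1L < insLen + 2L) return(NULL)
  lims
}

orfPreserved <- function(seq, orf) {
  found <- findLongestOrf(seq, minLenNt = 90L)
  !is.null(found) && found$orientation == orf$orientation &&
    found$start == orf$cdsStart && found$end == orf$cdsEnd
}

## Point-mutate the middle base of any background SSR run until none meeting
## the criteria remains, keeping planted ORFs intact.
disruptBackgroundSSRs <- function(seqs, orfTruth, criteria,
                                  maxRounds = 25L) {
  for (round in seq_len(maxRounds)) {
    loci <- findSSRs(seqs, criteria)
    if (length(loci) == 0L) return(seqs)
    for (i in seq_along(loci)) {
      tid <- as.character(GenomicRanges::seqnames(loci))[i]
      mid <- (GenomicRanges::start(loci)[i] + GenomicRanges::end(loci)[i]) %/%
        2L
      cur <- substr(seqs[[tid]], mid, mid)
      orf <- orfTruth[orfTruth$transcriptId == tid, ]
      for (b in sample(setdiff(BASES, cur))) {
        cand <- seqs[[tid]]
        substr(cand, mid, mid) <- b
        if (nrow(orf) == 1L) {
          if (orfPreserved(cand, orf)) { seqs[[tid]] <- cand; break }
        } else {
          if (is.null(findLongestOrf(cand, minLenNt = 90L))) {
            seqs[[tid]] <- cand; break
          }
        }
      }
    }
  }
  if (length(findSSRs(seqs, criteria)) > 0L)
    stop("could not remove background SSRs")
  seqs
}
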