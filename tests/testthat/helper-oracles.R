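## Independent reference implementations used to cross-check the package.
## These deliberately use different mechanisms from the package code
## (shifted-equality runs instead of regex scanning; per-position codon
## walking instead of frame tables; explicit matrix shrinking for UPGMA).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Brute-force perfect-SSR enumerator: for each unit length, find maximal
## periodic regions from the base-shifted equality vector, place the repeat
## leftmost, apply the same overlap-resolution convention.
bruteSSRs <- function(seq, minRepeats = c("2" = 6L, "3" = 5L, "4" = 4L,
                                          "5" = 4L, "6" = 3L)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ok <- ch %in% c("A", "C", "G", "T")
  cand <- list()
  for (pChr in names(minRepeats)) {
    p <- as.integer(pChr)
    if (n < 2L * p) next
    eq <- ch[seq_len(n - p)] == ch[(p + 1L):n] &
      ok[seq_len(n - p)] & ok[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]
      regionLen <- r$lengths[k] + p
      count <- regionLen %/% p
      if (count < minRepeats[[pChr]]) next
      motif <- paste(ch[i:(i + p - 1L)], collapse = "")
      prim <- TRUE
      for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            strrep(substr(motif, 1L, d), p %/% d) == motif) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = i, end = i + count * p - 1L, motif = motif, unit = p,
        count = count)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit = integer(0),
                      count = integer(0)))
  cand <- do.call(rbind, cand)
  width <- cand$end - cand$start + 1L
  cand <- cand[order(-width, cand$unit, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  used <- rep(FALSE, nchar(seq))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(used[span])) { keep[i] <- TRUE; used[span] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

ssrGrAsFrame <- function(gr) {
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             motif = S4Vectors::mcols(gr)$motif,
             count = S4Vectors::mcols(gr)$repeatCount)
}

## Brute-force longest ATG ORF: walk codons from every position on both
## strands.
bruteOrf <- function(seq, minLenNt = 90L) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  L <- nchar(seq)
  for (orient in c("FORWARD", "REVERSE")) {
    s <- if (orient == "FORWARD") seq else revcomp(seq)
    for (st in seq_len(L)) {
      if (substr(s, st, st + 2L) != "ATG") next
      pos <- st
      while (pos + 2L <= L) {
        cod <- substr(s, pos, pos + 2L)
        if (cod %in% stops) {
          len <- pos + 2L - st + 1L
          if (len >= minLenNt) {
            if (orient == "FORWARD") {
              cand <- list(start = st, end = pos + 2L, orientation = orient,
                           lengthNt = len)
            } else {
              cand <- list(start = L - (pos + 2L) + 1L, end = L - st + 1L,
                           orientation = orient, lengthNt = len)
            }
            better <- is.null(best) || len > best$lengthNt ||
              (len == best$lengthNt && best$orientation == "REVERSE" &&
               orient == "FORWARD") ||
              (len == best$lengthNt && best$orientation == orient &&
               cand$start < best$start)
            if (better) best <- cand
          }
          break
        }
        pos <- pos + 3L
      }
    }
  }
  best
}

## Exhaustive UPGMA reference: explicit matrix shrinking, returning the
## cophenetic (merge-distance) matrix over the original labels.
bruteUpgmaCophenetic <- function(D, labels = rownames(D)) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  reps <- labels
  sizes <- rep(1L, n)
  coph <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(coph) <- 0
  Dw <- D
  alive <- rep(TRUE, n)
  while (sum(alive) > 1L) {
    idx <- which(alive)
    best <- NULL
    for (a in idx) for (b in idx) {
      if (b <= a) next
      pr <- sort(c(reps[a], reps[b]))
      if (is.null(best) || Dw[a, b] < best$d - 1e-15 ||
          (abs(Dw[a, b] - best$d) <= 1e-15 &&
           (pr[1] < best$pr[1] ||
            (pr[1] == best$pr[1] && pr[2] < best$pr[2])))) {
        best <- list(a = a, b = b, d = Dw[a, b], pr = pr)
      }
    }
    a <- best$a; b <- best$b
    for (i in members[[a]]) for (j in members[[b]]) {
      coph[labels[i], labels[j]] <- coph[labels[j], labels[i]] <- best$d
    }
    for (k in idx) {
      if (k == a || k == b) next
      Dw[a, k] <- Dw[k, a] <-
        (sizes[a] * Dw[a, k] + sizes[b] * Dw[b, k]) / (sizes[a] + sizes[b])
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    reps[a] <- min(reps[a], reps[b])
    alive[b] <- FALSE
  }
  coph
}

randomSequence <- function(len, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomDistMatrix <- function(n, labels = paste0("t", seq_len(n))) {
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 2)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}
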