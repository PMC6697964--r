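#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_j^2)` over the allele frequencies of a locus: the
#' probability that two alleles drawn at random differ.
#'
#' @param frequencies nonnegative allele frequencies summing to 1
#'   (tolerance 1e-9).
#' @return PIC in `[0, 1 - 1/k]` for `k` alleles.
#' @export
picValue <- function(frequencies) {
  if (any(frequencies < 0)) stop("frequencies must be nonnegative")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must sum to 1 (tolerance 1e-9)")
  1 - sum(frequencies^2)
}

#' Allele frequencies of a locus from band presences
#'
#' The frequency of band j is its presence count divided by the total number
#' of band presences at the locus, so genotypes with a null allele (no band)
#' drop out of the denominator.
#'
#' @param matrix binary genotypes x bands matrix with column names
#'   `"locus:allele"`.
#' @param locus locus name (the part before the colon).
#' @return Named numeric frequencies over the locus's bands.
#' @export
locusFrequencies <- function(matrix, locus) {
  lociOfCol <- sub(":.*$", "", colnames(matrix))
  cols <- which(lociOfCol == locus)
  if (length(cols) == 0L) stop("locus '", locus, "' not present")
  counts <- colSums(matrix[, cols, drop = FALSE])
  tot <- sum(counts)
  if (tot == 0) stop("locus '", locus, "' has no band presences")
  counts / tot
}

#' Jaccard similarity of two binary band profiles
#'
#' `|x AND y| / |x OR y|`; two all-zero profiles (identical absence) are
#' defined as similarity 1.
#'
#' @param x,y equal-length binary vectors.
#' @return Similarity in `[0, 1]`.
#' @export
jaccardSimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  union <- sum(x | y)
  if (union == 0) return(1)
  sum(x & y) / union
}

#' Pairwise Jaccard distance matrix (1 - similarity)
#'
#' @param matrix binary genotypes x bands matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
jaccardDistanceMatrix <- function(matrix) {
  n <- nrow(matrix)
  D <- base::matrix(0, n, n, dimnames = list(rownames(matrix),
                                             rownames(matrix)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        D[i, j] <- D[j, i] <- 1 - jaccardSimilarity(matrix[i, ],
                                                    matrix[j, ])
      }
    }
  }
  D
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group method with arithmetic averages: the closest pair of
#' clusters is merged at a node of height = distance / 2, and distances to
#' the merged cluster are the size-weighted arithmetic averages of the
#' members' distances. Ties are broken deterministically in favour of the
#' pair whose (lexicographically smallest member label, then second label) is
#' smallest. The result is ultrametric by construction.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param labels tip labels (default from `D`'s dimnames).
#' @return An ape `phylo` tree with branch lengths (tip-to-root path lengths
#'   all equal).
#' @export
upgmaTree <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!isSymmetric(unname(D), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be nonnegative with zero diagonal")
  if (n == 1L) stop("need at least two taxa")
  clusters <- lapply(seq_len(n), function(i) {
    list(newick = labels[i], height = 0, size = 1L, rep = labels[i])
  })
  active <- seq_len(n)
  Dw <- D
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        d <- Dw[i, j]
        reps <- sort(c(clusters[[i]]$rep, clusters[[j]]$rep))
        cand <- list(i = i, j = j, d = d, reps = reps)
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (reps[1] < best$reps[1] ||
              (reps[1] == best$reps[1] && reps[2] < best$reps[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    ci <- clusters[[i]]; cj <- clusters[[j]]
    merged <- list(
      newick = sprintf("(%s:%.10g,%s:%.10g)", ci$newick, h - ci$height,
                       cj$newick, h - cj$height),
      height = h, size = ci$size + cj$size,
      rep = min(ci$rep, cj$rep))
    for (k in active) {
      if (k == i || k == j) next
      Dw[i, k] <- Dw[k, i] <-
        (ci$size * Dw[i, k] + cj$size * Dw[j, k]) / (ci$size + cj$size)
    }
    clusters[[i]] <- merged
    active <- setdiff(active, j)
  }
  root <- clusters[[active]]
  ape::read.tree(text = paste0(root$newick, ";"))
}

#' Per-locus and panel diversity summary
#'
#' Computes allele counts, frequencies and PIC per locus, panel summaries
#' (mean alleles/locus; PIC min/mean/max), the pairwise Jaccard distance
#' matrix (1 - similarity) and its UPGMA dendrogram, all from one band
#' presence/absence matrix.
#'
#' @param matrix binary genotypes x bands matrix, band columns named
#'   `"locus:allele"`.
#' @return A `DiversitySummary` list: `locusStats` (data.frame `locus`,
#'   `alleleCount`, `pic`, with frequencies as a list attribute),
#'   `frequencies` (per-locus list), `panel` (`meanAllelesPerLocus`,
#'   `picMin`, `picMean`, `picMax`), `distance` (matrix), `tree` (`phylo`).
#' @export
summarizeDiversity <- function(matrix) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) stop("empty band matrix")
  loci <- unique(sub(":.*$", "", colnames(matrix)))
  freqs <- lapply(loci, function(l) locusFrequencies(matrix, l))
  names(freqs) <- loci
  locusStats <- data.frame(
    locus = loci,
    alleleCount = vapply(freqs, length, integer(1)),
    pic = vapply(freqs, picValue, numeric(1)),
    row.names = NULL)
  D <- jaccardDistanceMatrix(matrix)
  structure(list(
    locusStats = locusStats,
    frequencies = freqs,
    panel = list(meanAllelesPerLocus = mean(locusStats$alleleCount),
                 picMin = min(locusStats$pic),
                 picMean = mean(locusStats$pic),
                 picMax = max(locusStats$pic)),
    distance = D,
    tree = upgmaTree(D)), class = "DiversitySummary")
}

#' @export
print.DiversitySummary <- function(x, ...) {
  cat("Diversity panel:", nrow(x$distance), "genotypes,",
      nrow(x$locusStats), "loci,", sum(x$locusStats$alleleCount),
      "alleles\n")
  cat(sprintf("  alleles/locus mean %.1f; PIC %.2f-%.2f, mean %.2f\n",
              x$panel$meanAllelesPerLocus, x$panel$picMin, x$panel$picMax,
              x$panel$picMean))
  invisible(x)
}

#' Write diversity outputs
#'
#' Writes the per-locus statistics (PIC to 2 decimals), the distance matrix
#' and the dendrogram in newick format.
#'
#' @param summary a `DiversitySummary`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeDiversity <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stats <- summary$locusStats
  stats$pic <- round(stats$pic, 2)
  write.table(stats, file.path(dir, "locus_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(round(summary$distance, 4),
              file.path(dir, "jaccard_distance.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  ape::write.tree(summary$tree, file.path(dir, "upgma.nwk"))
  invisible(dir)
}
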