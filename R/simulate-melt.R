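#' Homoduplex melting temperatures by base identity
#'
#' Auto-assigns homoduplex Tm offsets that respect the duplex stability
#' ordering A/A < T/T < C/C < G/G predicted by nearest-neighbour
#' thermodynamics.
#'
#' @param base one of A/C/G/T (the variant base carried by the homozygote).
#' @param baseTm Tm of the least stable (A/A) duplex (degrees C).
#' @param step Tm increment between successive stability ranks.
#' @return Numeric Tm in degrees C.
#' @export
homoduplexTm <- function(base, baseTm = 80, step = 0.4) {
  rank <- c(A = 0, T = 1, C = 2, G = 3)
  if (!all(base %in% names(rank))) stop("base must be one of A/C/G/T")
  baseTm + step * unname(rank[base])
}

#' Simulate a melt curve
#'
#' Two-state (logistic) melting with linear pre- and post-melt baselines:
#' the helical fraction is `1 - sum_k w_k * sigmoid((T - Tm_k)/width)` and the
#' fluorescence interpolates between the sloped upper and lower baselines,
#' plus Gaussian noise. Homozygous templates are one duplex species; a
#' heterozygote is a mixture of two homoduplex and two heteroduplex species
#' with the heteroduplex Tms depressed below both homoduplex Tms.
#'
#' @param tmValues melt temperatures of the duplex species (degrees C).
#' @param weights nonnegative species weights summing to 1 (tolerance 1e-9).
#' @param transitionWidth logistic width parameter (degrees C).
#' @param noiseSd Gaussian noise standard deviation as a fraction of the melt
#'   amplitude.
#' @param tempGrid ascending uniform temperature grid spanning all `tmValues`
#'   with at least 5 degrees C margin.
#' @param ct,efficiency amplification QC metrics carried on the curve.
#' @param sampleId sample identifier.
#' @param amplitude melt amplitude in fluorescence units.
#' @param upperSlope,lowerSlope baseline slopes (units per degree C).
#' @param seed integer seed.
#' @return A [MeltCurve-class].
#' @export
simulateMeltCurve <- function(tmValues, weights = rep(1 / length(tmValues),
                                                      length(tmValues)),
                              transitionWidth = 0.35, noiseSd = 0,
                              tempGrid = seq(65, 95, by = 0.1),
                              ct = 22, efficiency = 1.8,
                              sampleId = "sample", amplitude = 100,
                              upperSlope = -0.08, lowerSlope = -0.02,
                              seed = 1L) {
  if (length(weights) != length(tmValues))
    stop("weights and tmValues must have equal length")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (transitionWidth <= 0) stop("transitionWidth must be positive")
  if (min(tmValues) - min(tempGrid) < 5 || max(tempGrid) - max(tmValues) < 5)
    stop("tempGrid must span all tmValues with >= 5 C margin")
  withSeed(seedFor(seed, paste0("simulate_melt_curve/", sampleId)), {
    t0 <- min(tempGrid)
    melted <- rowSums(vapply(seq_along(tmValues), function(k) {
      weights[k] / (1 + exp(-(tempGrid - tmValues[k]) / transitionWidth))
    }, numeric(length(tempGrid))))
    upper <- amplitude + 10 + upperSlope * (tempGrid - t0)
    lower <- 5 + lowerSlope * (tempGrid - t0)
    f <- lower + (upper - lower) * (1 - melted)
    if (noiseSd > 0) f <- f + rnorm(length(f), 0, noiseSd * amplitude)
    meltCurve(sampleId, tempGrid, f, ct = ct, efficiency = efficiency)
  })
}

#' Simulate a melt curve for a genotype at a SNP site
#'
#' Convenience wrapper that auto-assigns duplex Tms from base identity. A
#' homozygote gives a single species at [homoduplexTm()] of its base; a
#' heterozygote gives the two homoduplex species plus two heteroduplex
#' species placed `hetDepression` (and an extra 0.3 C for the second) below
#' the less stable homoduplex, with default weights 0.25 each.
#'
#' @param genotype two bases, e.g. `c("A", "A")` or `"A/G"`.
#' @param hetDepression heteroduplex Tm depression below the less stable
#'   homoduplex (degrees C, default 1.5).
#' @param baseTm,step passed to [homoduplexTm()].
#' @param ... passed to [simulateMeltCurve()].
#' @return A [MeltCurve-class].
#' @export
simulateGenotypeCurve <- function(genotype, hetDepression = 1.5,
                                  baseTm = 80, step = 0.4, ...) {
  if (length(genotype) == 1L)
    genotype <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  if (length(genotype) != 2L || !all(genotype %in% BASES))
    stop("genotype must be two bases from A/C/G/T")
  if (genotype[1] == genotype[2]) {
    simulateMeltCurve(homoduplexTm(genotype[1], baseTm, step), ...)
  } else {
    homTms <- homoduplexTm(genotype, baseTm, step)
    hetTms <- min(homTms) - hetDepression - c(0, 0.3)
    simulateMeltCurve(c(homTms, hetTms), weights = rep(0.25, 4), ...)
  }
}

#' Write melt curves as a long-format TSV
#'
#' Emits `sample`, `temperature`, `fluorescence` columns plus a per-sample
#' QC table (`sample`, `ct`, `efficiency`).
#'
#' @param curves list of [MeltCurve-class] objects.
#' @param path curve TSV path.
#' @param qcPath QC TSV path (default `paste0(path, ".qc")`).
#' @return The curve path, invisibly.
#' @export
writeMeltCurves <- function(curves, path, qcPath = paste0(path, ".qc")) {
  long <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample = sampleId(cv), temperature = temperatures(cv),
               fluorescence = fluorescence(cv))
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  qc <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample = sampleId(cv), ct = ctValue(cv),
               efficiency = amplificationEfficiency(cv))
  }))
  write.table(qc, qcPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read melt curves from a long-format TSV
#'
#' @param path curve TSV (`sample`, `temperature`, `fluorescence`).
#' @param qcPath optional QC TSV (`sample`, `ct`, `efficiency`).
#' @return A named list of [MeltCurve-class] objects.
#' @export
readMeltCurves <- function(path, qcPath = NULL) {
  long <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  qc <- if (!is.null(qcPath) && file.exists(qcPath)) {
    read.table(qcPath, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else NULL
  out <- lapply(split(long, long$sample), function(d) {
    d <- d[order(d$temperature), ]
    ct <- eff <- NA_real_
    if (!is.null(qc)) {
      row <- qc[qc$sample == d$sample[1], ]
      if (nrow(row) == 1L) { ct <- row$ct; eff <- row$efficiency }
    }
    meltCurve(d$sample[1], d$temperature, d$fluorescence, ct, eff)
  })
  out[order(names(out))]
}
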