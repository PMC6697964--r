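#' Amplification quality control for a melt curve
#'
#' A run passes QC iff its Ct value is at most `ctMax` and its amplification
#' efficiency is strictly greater than `effMin` (Ct <= 30 with
#' efficiency > 1.4 by default).
#'
#' @param curve a [MeltCurve-class].
#' @param ctMax maximum acceptable Ct (inclusive).
#' @param effMin efficiency lower bound (exclusive).
#' @return A list: `pass` (logical) and `reason` (NA when passing).
#' @export
qcFilter <- function(curve, ctMax = 30, effMin = 1.4) {
  ct <- ctValue(curve); eff <- amplificationEfficiency(curve)
  if (is.na(ct) || is.na(eff))
    return(list(pass = FALSE, reason = "missing-qc-field"))
  if (ct > ctMax) return(list(pass = FALSE, reason = "ct-too-high"))
  if (eff <= effMin)
    return(list(pass = FALSE, reason = "efficiency-too-low"))
  list(pass = TRUE, reason = NA_character_)
}

#' Normalize a melt curve to the percent scale
#'
#' Fits linear baselines to the pre-melt and post-melt temperature windows
#' and rescales the trace to `100 * (F - lower) / (upper - lower)`, clipped
#' to `[0, 100]`, so the pre-melt window averages 100 and the post-melt
#' window 0.
#'
#' @param curve a [MeltCurve-class].
#' @param preWindow,postWindow temperature intervals `c(from, to)` for the
#'   baseline fits; defaults are the first and last 2 degrees C of the grid.
#' @return A normalized [MeltCurve-class].
#' @export
normalizeCurve <- function(curve, preWindow = NULL, postWindow = NULL) {
  tt <- temperatures(curve); ff <- fluorescence(curve)
  if (is.null(preWindow)) preWindow <- c(min(tt), min(tt) + 2)
  if (is.null(postWindow)) postWindow <- c(max(tt) - 2, max(tt))
  if (preWindow[2] >= postWindow[1])
    stop("pre-melt window must end before the post-melt window starts")
  pre <- tt >= preWindow[1] & tt <= preWindow[2]
  post <- tt >= postWindow[1] & tt <= postWindow[2]
  if (sum(pre) < 2L || sum(post) < 2L)
    stop("baseline windows must contain at least two grid points")
  fitU <- lm(f ~ t, data = data.frame(t = tt[pre], f = ff[pre]))
  fitL <- lm(f ~ t, data = data.frame(t = tt[post], f = ff[post]))
  upper <- predict(fitU, newdata = data.frame(t = tt))
  lower <- predict(fitL, newdata = data.frame(t = tt))
  gap <- upper - lower
  if (mean(gap) < 1e-8 * max(abs(ff), 1))
    stop("degenerate baselines: upper and lower coincide (flat curve?)")
  norm <- 100 * (ff - lower) / gap
  norm <- pmin(pmax(norm, 0), 100)
  meltCurve(sampleId(curve), tt, norm, ctValue(curve),
            amplificationEfficiency(curve), normalized = TRUE)
}

#' Melt domains from the negative-derivative plot
#'
#' Computes the smoothed negative derivative -dF/dT by central finite
#' differences plus a moving-average filter, then reports every local maximum
#' whose height exceeds `minProminenceFrac` of the global maximum and that is
#' separated from any larger retained peak by at least `minSeparation`
#' degrees C. Each peak temperature is refined by quadratic interpolation
#' through the three grid points around the maximum.
#'
#' @param curve a normalized [MeltCurve-class].
#' @param smoothWindow moving-average width in grid points (odd; default 11).
#' @param minProminenceFrac peak height threshold as a fraction of the
#'   global maximum (default 0.1).
#' @param minSeparation minimum peak separation in degrees C (default 0.5).
#' @return A data.frame with one row per melt domain: `tm` (degrees C) and
#'   `height`, ordered by descending height.
#' @export
meltDomains <- function(curve, smoothWindow = 11L, minProminenceFrac = 0.1,
                        minSeparation = 0.5) {
  tt <- temperatures(curve); ff <- fluorescence(curve)
  n <- length(tt)
  if (n < max(smoothWindow, 5L))
    stop("curve shorter than the smoothing window")
  step <- tt[2] - tt[1]
  deriv <- c(NA, -(ff[3:n] - ff[1:(n - 2)]) / (2 * step), NA)
  deriv[1] <- deriv[2]; deriv[n] <- deriv[n - 1]
  k <- as.integer(smoothWindow)
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::filter(deriv, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  half <- k %/% 2L
  sm[seq_len(half)] <- sm[half + 1L]
  sm[(n - half + 1L):n] <- sm[n - half]
  gmax <- max(sm)
  empty <- data.frame(tm = numeric(0), height = numeric(0))
  if (!is.finite(gmax) || gmax <= 1e-9) return(empty)
  isPeak <- which(sm[2:(n - 1)] >= sm[1:(n - 2)] &
                  sm[2:(n - 1)] >= sm[3:n]) + 1L
  isPeak <- isPeak[sm[isPeak] >= minProminenceFrac * gmax]
  if (length(isPeak) == 0L) return(empty)
  ## drop duplicate flat-top indices, then enforce separation greedily from
  ## the highest peak down
  isPeak <- isPeak[c(TRUE, diff(isPeak) > 1L)]
  ord <- isPeak[order(-sm[isPeak])]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(tt[p] - tt[kept]) >= minSeparation)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  tm <- vapply(kept, function(p) {
    if (p <= 1L || p >= n) return(tt[p])
    y <- sm[(p - 1L):(p + 1L)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (abs(denom) < 1e-12) return(tt[p])
    tt[p] + 0.5 * step * (y[1] - y[3]) / denom
  }, numeric(1))
  out <- data.frame(tm = tm, height = sm[kept])
  out[order(-out$height), , drop = FALSE]
}

#' Call zygosity from a raw melt curve
#'
#' Applies [qcFilter()], [normalizeCurve()] and [meltDomains()] and maps the
#' melt-domain count to a genotype call: one domain is homozygous, two or
#' more heterozygous (heteroduplex mixture), zero no-call. QC failures give
#' `NO_CALL` with `qcPass = FALSE`.
#'
#' @param curve a raw [MeltCurve-class].
#' @param ctMax,effMin passed to [qcFilter()].
#' @param preWindow,postWindow passed to [normalizeCurve()].
#' @param smoothWindow,minProminenceFrac,minSeparation passed to
#'   [meltDomains()].
#' @return A `GenotypeCall` list: `sampleId`, `nMeltDomains`, `zygosity`
#'   (`HOMOZYGOUS`/`HETEROZYGOUS`/`NO_CALL`), `tmValues` (descending peak
#'   height order), `qcPass`, `qcReason`.
#' @export
callGenotype <- function(curve, ctMax = 30, effMin = 1.4, preWindow = NULL,
                         postWindow = NULL, smoothWindow = 11L,
                         minProminenceFrac = 0.1, minSeparation = 0.5) {
  qc <- qcFilter(curve, ctMax, effMin)
  if (!qc$pass) {
    return(structure(list(sampleId = sampleId(curve), nMeltDomains = 0L,
                          zygosity = "NO_CALL", tmValues = numeric(0),
                          qcPass = FALSE, qcReason = qc$reason),
                     class = "GenotypeCall"))
  }
  norm <- normalizeCurve(curve, preWindow, postWindow)
  domains <- meltDomains(norm, smoothWindow, minProminenceFrac,
                         minSeparation)
  nd <- nrow(domains)
  zyg <- if (nd == 0L) "NO_CALL" else if (nd == 1L) "HOMOZYGOUS" else
    "HETEROZYGOUS"
  structure(list(sampleId = sampleId(curve), nMeltDomains = nd,
                 zygosity = zyg, tmValues = domains$tm, qcPass = TRUE,
                 qcReason = NA_character_), class = "GenotypeCall")
}

#' @export
print.GenotypeCall <- function(x, ...) {
  cat("GenotypeCall '", x$sampleId, "': ", x$zygosity, " (",
      x$nMeltDomains, " melt domain(s)",
      if (x$nMeltDomains > 0)
        paste0(", Tm ", paste(sprintf("%.2f", x$tmValues), collapse = "/")),
      if (!x$qcPass) paste0("; QC fail: ", x$qcReason), ")\n", sep = "")
  invisible(x)
}

## Printed per-class Tm-difference ranges (degrees C) used as an annotation
## on pair comparisons.
HRM_CLASS_TM_RANGES <- list(I = c(0.15, 0.51), II = c(0.03, 0.41),
                            III = c(0.18, 0.35), IV = c(0.02, 0.12))

#' Compare two homozygous genotype calls
#'
#' Reports the absolute Tm difference between two homozygous samples, the
#' HRM SNP class of the substitution when the bases are given, and whether
#' the observed difference lies within the class's reported Tm-difference
#' range (annotation only; calls are never altered by it).
#'
#' @param callA,callB `GenotypeCall`s, both homozygous with one Tm each.
#' @param snpBases optional `c(ref, alt)` bases of the SNP.
#' @return A `PairComparison` list: `samples`, `deltaTm`, `snpClass` (NA
#'   without bases), `classRangeConsistent` (NA without bases).
#' @export
comparePair <- function(callA, callB, snpBases = NULL) {
  for (cl in list(callA, callB)) {
    if (cl$zygosity != "HOMOZYGOUS" || length(cl$tmValues) != 1L)
      stop("comparePair needs two homozygous calls with a single Tm each")
  }
  deltaTm <- abs(callA$tmValues - callB$tmValues)
  snpClass <- NA_character_
  consistent <- NA
  if (!is.null(snpBases)) {
    snpClass <- hrmClass(snpBases[1], snpBases[2])
    rng <- HRM_CLASS_TM_RANGES[[snpClass]]
    consistent <- deltaTm >= rng[1] && deltaTm <= rng[2]
  }
  structure(list(samples = c(callA$sampleId, callB$sampleId),
                 deltaTm = deltaTm, snpClass = snpClass,
                 classRangeConsistent = consistent),
            class = "PairComparison")
}

#' Genotype a set of melt curves
#'
#' @param curves list of raw [MeltCurve-class] objects.
#' @param ... passed to [callGenotype()].
#' @return A data.frame with one row per sample: `sampleId`, `zygosity`,
#'   `nMeltDomains`, `tm1`, `tm2`, `qcPass`.
#' @export
callGenotypes <- function(curves, ...) {
  do.call(rbind, lapply(curves, function(cv) {
    call <- callGenotype(cv, ...)
    data.frame(sampleId = call$sampleId, zygosity = call$zygosity,
               nMeltDomains = call$nMeltDomains,
               tm1 = if (length(call$tmValues) >= 1) call$tmValues[1]
                     else NA_real_,
               tm2 = if (length(call$tmValues) >= 2) call$tmValues[2]
                     else NA_real_,
               qcPass = call$qcPass, row.names = NULL)
  }))
}
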