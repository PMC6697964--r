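#' MeltCurve: a temperature-indexed fluorescence trace
#'
#' Container for one sample's high-resolution-melting trace together with its
#' amplification quality metrics (Ct and per-cycle amplification efficiency),
#' which gate whether the curve may be genotyped at all.
#'
#' @slot sampleId sample identifier.
#' @slot temperatures ascending uniform temperature grid (degrees C).
#' @slot fluorescence fluorescence readings (arbitrary units), one per
#'   temperature.
#' @slot ct PCR cycle-threshold value.
#' @slot efficiency per-cycle amplification factor.
#' @slot normalized whether the trace is on the 0-100 percent scale.
#' @export
setClass("MeltCurve",
         representation(sampleId = "character", temperatures = "numeric",
                        fluorescence = "numeric", ct = "numeric",
                        efficiency = "numeric", normalized = "logical"))

setValidity("MeltCurve", function(object) {
  msgs <- character(0)
  if (length(object@temperatures) != length(object@fluorescence))
    msgs <- c(msgs, "temperatures and fluorescence must have equal length")
  if (length(object@temperatures) >= 2) {
    steps <- diff(object@temperatures)
    if (any(steps <= 0)) msgs <- c(msgs, "temperature grid must be ascending")
    if (length(steps) >= 2 && max(steps) - min(steps) > 1e-6)
      msgs <- c(msgs, "temperature grid step must be constant (within 1e-6)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MeltCurve
#'
#' @param sampleId sample identifier.
#' @param temperatures ascending uniform grid (degrees C).
#' @param fluorescence fluorescence values, same length.
#' @param ct cycle-threshold value (default NA).
#' @param efficiency amplification efficiency (default NA).
#' @param normalized logical; TRUE when on the percent scale.
#' @return A validated [MeltCurve-class] object.
#' @export
meltCurve <- function(sampleId, temperatures, fluorescence, ct = NA_real_,
                      efficiency = NA_real_, normalized = FALSE) {
  new("MeltCurve", sampleId = as.character(sampleId),
      temperatures = as.numeric(temperatures),
      fluorescence = as.numeric(fluorescence), ct = as.numeric(ct),
      efficiency = as.numeric(efficiency), normalized = normalized)
}

#' @describeIn MeltCurve-class sample identifier
#' @param object,x a `MeltCurve`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname MeltCurve-class
#' @export
setMethod("sampleId", "MeltCurve", function(x) x@sampleId)

#' @rdname MeltCurve-class
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @rdname MeltCurve-class
#' @export
setMethod("temperatures", "MeltCurve", function(x) x@temperatures)

#' @rdname MeltCurve-class
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))
#' @rdname MeltCurve-class
#' @export
setMethod("fluorescence", "MeltCurve", function(x) x@fluorescence)

#' @rdname MeltCurve-class
#' @export
setGeneric("ctValue", function(x) standardGeneric("ctValue"))
#' @rdname MeltCurve-class
#' @export
setMethod("ctValue", "MeltCurve", function(x) x@ct)

#' @rdname MeltCurve-class
#' @export
setGeneric("amplificationEfficiency",
           function(x) standardGeneric("amplificationEfficiency"))
#' @rdname MeltCurve-class
#' @export
setMethod("amplificationEfficiency", "MeltCurve", function(x) x@efficiency)

setMethod("show", "MeltCurve", function(object) {
  tr <- object@temperatures
  cat("MeltCurve '", object@sampleId, "': ", length(tr), " points, ",
      if (length(tr)) sprintf("%.1f-%.1f C", min(tr), max(tr)) else "empty",
      if (object@normalized) " (normalized)" else " (raw)",
      sprintf(", Ct=%.1f, eff=%.2f", object@ct, object@efficiency), "\n",
      sep = "")
})
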