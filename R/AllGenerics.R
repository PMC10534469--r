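#' @include AllClasses.R
NULL

#' Accessors for emgfatigue classes
#'
#' Small accessor generics: slot access from user code should go through
#' these rather than `@`.
#'
#' @param object an emgfatigue S4 object.
#' @return The corresponding slot value; `featureTable` and `trendTable`
#'   return `data.frame`s.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(object) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("recordingPhase", function(object) standardGeneric("recordingPhase"))
#' @rdname accessors
#' @export
setGeneric("recordingEvents", function(object) standardGeneric("recordingEvents"))
#' @rdname accessors
#' @export
setGeneric("signalUnits", function(object) standardGeneric("signalUnits"))
#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("mvcValue", function(object) standardGeneric("mvcValue"))
#' @rdname accessors
#' @export
setGeneric("plateauBounds", function(object) standardGeneric("plateauBounds"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("trendRho", function(object) standardGeneric("trendRho"))
#' @rdname accessors
#' @export
setGeneric("trendPValue", function(object) standardGeneric("trendPValue"))
#' @rdname accessors
#' @export
setGeneric("isFatigued", function(object) standardGeneric("isFatigued"))
#' @rdname accessors
#' @export
setGeneric("agreementTests", function(object) standardGeneric("agreementTests"))
#' @rdname accessors
#' @export
setGeneric("similarFraction", function(object) standardGeneric("similarFraction"))

#' @rdname accessors
setMethod("samples", "Recording", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(object) object@rate)
#' @rdname accessors
setMethod("recordingDuration", "Recording",
          function(object) length(object@samples) / object@rate)
#' @rdname accessors
setMethod("recordingPhase", "Recording", function(object) object@phase)
#' @rdname accessors
setMethod("recordingEvents", "Recording", function(object) object@events)
#' @rdname accessors
setMethod("signalUnits", "Recording", function(object) object@units)
#' @rdname accessors
setMethod("participantId", "Recording", function(object) object@participantId)

#' @rdname accessors
setMethod("mvcValue", "MvcResult", function(object) object@mvcValue)
#' @rdname accessors
setMethod("plateauBounds", "MvcResult", function(object) object@plateauBounds)

#' @rdname accessors
setMethod("featureTable", "FeatureSeries", function(object)
  data.frame(window_start_s = object@windowStart, rms_pct_mvc = object@rms,
             mdf_hz = object@mdf, mnf_hz = object@mnf,
             defined = object@defined))

#' @rdname accessors
setMethod("trendRho", "TrendResult", function(object) object@rho)
#' @rdname accessors
setMethod("trendPValue", "TrendResult", function(object) object@pValue)

#' @rdname accessors
setMethod("isFatigued", "FatigueCall", function(object) object@fatigued)
#' @rdname accessors
setMethod("trendRho", "FatigueCall", function(object)
  vapply(object@trends, slot, numeric(1), "rho"))

#' @rdname accessors
setMethod("agreementTests", "DeviceComparison", function(object) object@tests)
#' @rdname accessors
setMethod("similarFraction", "DeviceComparison", function(object) object@similarFraction)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d samples @ %g Hz (%.2f s), phase=%s, units=%s\n",
              length(object@samples), object@rate,
              recordingDuration(object), object@phase, object@units))
  if (!is.na(object@participantId))
    cat("  participant:", object@participantId, "\n")
  if (nrow(object@events))
    cat(sprintf("  %d event marker(s): %s\n", nrow(object@events),
                paste(sprintf("%s@%.2fs", object@events$label,
                              object@events$time_s), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "FilterSpec: Butterworth band-pass %g-%g Hz (order %d), notch comb %g Hz Q=%g, %s\n",
    object@bandLow, object@bandHigh, object@order, object@notchBase,
    object@notchQ, if (object@zeroPhase) "zero-phase" else "causal"))
  invisible(NULL)
})

setMethod("show", "FeatureSeries", function(object) {
  cat(sprintf("FeatureSeries (%s): %d windows, %d defined\n",
              object@kind, length(object@windowStart), sum(object@defined)))
  if (length(object@windowStart))
    print(utils::head(featureTable(object), 4))
  invisible(NULL)
})

setMethod("show", "MvcResult", function(object) {
  cat(sprintf("MvcResult: MVC = %g (trial medians %s)\n", object@mvcValue,
              paste(signif(object@perTrialMedianRms, 4), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf("TrendResult[%s]: rho = %s, p = %s (n = %d windows)\n",
              object@feature, format(object@rho, digits = 3),
              format(object@pValue, digits = 3), object@nWindows))
  invisible(NULL)
})

setMethod("show", "FatigueCall", function(object) {
  state <- if (is.na(object@fatigued)) "undetermined"
           else if (object@fatigued) "FATIGUED" else "not fatigued"
  cat("FatigueCall:", state, "\n")
  for (tr in object@trends) show(tr)
  cat("  rule:", object@rule, "\n")
  invisible(NULL)
})

setMethod("show", "DeviceComparison", function(object) {
  cat(sprintf("DeviceComparison: %d participants, %.2f%% sign-concordant\n",
              nrow(object@coefA), object@similarFraction))
  print(object@tests)
  invisible(NULL)
})

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(
    "SynthParams: %g s @ %g Hz, %s envelope, bandwidth %g Hz, mains %g, bits %s, seed %d\n",
    object@durationS, object@rate, object@envelope, object@bandwidth,
    object@mainsAmp, ifelse(is.na(object@quantBits), "none", object@quantBits),
    object@seed))
  invisible(NULL)
})
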