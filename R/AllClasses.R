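#' @import methods
NULL

.PHASES <- c("mvc", "isometric", "isotonic")
.UNITS <- c("raw", "volts", "percent_mvc")
.FEATURE_NAMES <- c("rms", "mdf", "mnf")

#' Single-channel EMG recording
#'
#' An S4 container for one sampled surface-EMG channel together with its
#' sampling rate, experimental phase, event markers (e.g. the press of a
#' fatigue button) and participant metadata.
#'
#' @slot samples numeric vector of sample values.
#' @slot rate sampling rate in Hz (positive scalar; 2000 Hz in the protocol
#'   this package targets).
#' @slot phase one of `"mvc"`, `"isometric"`, `"isotonic"`.
#' @slot events `data.frame` with columns `time_s` (seconds from recording
#'   start) and `label`; every event time must lie within the recording.
#' @slot participantId opaque participant identifier.
#' @slot units one of `"raw"`, `"volts"`, `"percent_mvc"`. Unit changes are
#'   always explicit operations, never side effects of I/O.
#'
#' @seealso [Recording()] for the user-facing constructor,
#'   [readWav()], [readCsvSignal()].
#' @export
setClass("Recording",
  representation(
    samples = "numeric",
    rate = "numeric",
    phase = "character",
    events = "data.frame",
    participantId = "character",
    units = "character"
  ),
  prototype(
    samples = numeric(0),
    rate = 2000,
    phase = "isometric",
    events = data.frame(time_s = numeric(0), label = character(0)),
    participantId = NA_character_,
    units = "raw"
  )
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive finite number")
  if (length(object@phase) != 1L || !(object@phase %in% .PHASES))
    msg <- c(msg, sprintf("'phase' must be one of: %s", paste(.PHASES, collapse = ", ")))
  if (length(object@units) != 1L || !(object@units %in% .UNITS))
    msg <- c(msg, sprintf("'units' must be one of: %s", paste(.UNITS, collapse = ", ")))
  if (!all(c("time_s", "label") %in% names(object@events)))
    msg <- c(msg, "'events' must have columns 'time_s' and 'label'")
  else if (nrow(object@events) > 0) {
    dur <- length(object@samples) / object@rate
    if (any(object@events$time_s < 0 | object@events$time_s > dur))
      msg <- c(msg, "every event time must lie within [0, duration]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric vector of sample values.
#' @param rate sampling rate in Hz.
#' @param phase contraction phase label: `"mvc"`, `"isometric"` or
#'   `"isotonic"`.
#' @param events `data.frame` with columns `time_s` and `label`, or `NULL`.
#' @param participantId participant identifier.
#' @param units sample units: `"raw"`, `"volts"` or `"percent_mvc"`.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(sin(2 * pi * 100 * seq(0, 1, by = 1 / 2000)), rate = 2000)
#' recordingDuration(rec)
#' @export
Recording <- function(samples, rate = 2000, phase = "isometric", events = NULL,
                      participantId = NA_character_, units = "raw") {
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), label = character(0))
  new("Recording",
    samples = as.numeric(samples), rate = as.numeric(rate),
    phase = phase, events = events,
    participantId = as.character(participantId), units = units)
}

#' Filter chain specification
#'
#' Parameters of the preprocessing chain: a Butterworth band-pass (20-450 Hz
#' by default, 4th-order prototype) followed by a comb of Butterworth notch
#' sections at the mains frequency and its harmonics.
#'
#' @slot bandLow lower band edge, Hz.
#' @slot bandHigh upper band edge, Hz.
#' @slot order band-pass prototype order (before any forward-backward
#'   doubling).
#' @slot notchBase mains base frequency, Hz (60 in the Americas).
#' @slot notchQ quality factor of each notch section (bandwidth = f0 / Q).
#' @slot zeroPhase if `TRUE` (default) filters run forward-backward so window
#'   timestamps are not delayed; `FALSE` gives the causal single-pass filter.
#' @export
setClass("FilterSpec",
  representation(
    bandLow = "numeric", bandHigh = "numeric", order = "integer",
    notchBase = "numeric", notchQ = "numeric", zeroPhase = "logical"
  ),
  prototype(bandLow = 20, bandHigh = 450, order = 4L,
            notchBase = 60, notchQ = 30, zeroPhase = TRUE)
)

setValidity("FilterSpec", function(object) {
  msg <- character(0)
  if (!(object@bandLow > 0 && object@bandLow < object@bandHigh))
    msg <- c(msg, "need 0 < bandLow < bandHigh")
  if (object@order < 1L) msg <- c(msg, "'order' must be >= 1")
  if (object@notchBase <= 0) msg <- c(msg, "'notchBase' must be positive")
  if (object@notchQ <= 0) msg <- c(msg, "'notchQ' must be positive")
  if (length(msg)) msg else TRUE
})

#' @param bandLow,bandHigh band-pass edges in Hz.
#' @param order band-pass prototype order.
#' @param notchBase,notchQ mains notch base frequency (Hz) and section Q.
#' @param zeroPhase logical; forward-backward filtering.
#' @return A [FilterSpec-class] object.
#' @rdname FilterSpec-class
#' @export
filterSpec <- function(bandLow = 20, bandHigh = 450, order = 4L,
                       notchBase = 60, notchQ = 30, zeroPhase = TRUE) {
  new("FilterSpec", bandLow = as.numeric(bandLow), bandHigh = as.numeric(bandHigh),
      order = as.integer(order), notchBase = as.numeric(notchBase),
      notchQ = as.numeric(notchQ), zeroPhase = isTRUE(zeroPhase))
}

#' One-sided power spectrum of a signal window
#'
#' @slot freqs ascending non-negative frequency grid, Hz.
#' @slot power non-negative spectral power per bin, normalized so that
#'   `sum(power)` equals the mean square of the demeaned source window
#'   (Parseval).
#' @export
setClass("EmgSpectrum",
  representation(freqs = "numeric", power = "numeric"))

setValidity("EmgSpectrum", function(object) {
  msg <- character(0)
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "'freqs' and 'power' must have equal length")
  if (length(object@freqs) && (is.unsorted(object@freqs) || any(object@freqs < 0)))
    msg <- c(msg, "'freqs' must be non-negative and ascending")
  if (any(object@power < 0)) msg <- c(msg, "'power' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-window feature series
#'
#' Windowed features of one recording: RMS amplitude in %MVC, median power
#' frequency (MDF) and mean power frequency (MNF) per analysis window.
#' Windows whose features are undefined (zero spectral power, silent
#' contraction gaps) carry `NA` and are flagged in `defined`.
#'
#' @slot windowStart window start times in seconds (half-open windows
#'   `[start, start + length)`).
#' @slot rms RMS amplitude per window, %MVC (or raw units when no MVC was
#'   supplied).
#' @slot mdf median power frequency per window, Hz.
#' @slot mnf mean power frequency per window, Hz.
#' @slot defined logical; `FALSE` marks degenerate windows.
#' @slot kind `"isometric"` (plain per-window FFT) or `"isotonic_averaged"`
#'   (smoothed instantaneous frequencies averaged per second).
#' @export
setClass("FeatureSeries",
  representation(
    windowStart = "numeric", rms = "numeric", mdf = "numeric",
    mnf = "numeric", defined = "logical", kind = "character"
  ))

setValidity("FeatureSeries", function(object) {
  n <- length(object@windowStart)
  msg <- character(0)
  if (!all(lengths(list(object@rms, object@mdf, object@mnf, object@defined)) == n))
    msg <- c(msg, "all feature slots must share the length of 'windowStart'")
  if (n > 1 && is.unsorted(object@windowStart, strictly = TRUE))
    msg <- c(msg, "'windowStart' must be strictly ascending")
  if (!(object@kind %in% c("isometric", "isotonic_averaged")))
    msg <- c(msg, "'kind' must be 'isometric' or 'isotonic_averaged'")
  if (length(msg)) msg else TRUE
})

#' Maximal-voluntary-contraction estimate
#'
#' @slot perTrialMedianRms median plateau RMS of each of the three MVC trials.
#' @slot mvcValue the MVC: maximum of the three trial medians.
#' @slot plateauBounds 3 x 2 matrix of (start_s, end_s) plateau bounds per
#'   trial, reported so a user can inspect or override the automatic crop.
#' @export
setClass("MvcResult",
  representation(perTrialMedianRms = "numeric", mvcValue = "numeric",
                 plateauBounds = "matrix"))

setValidity("MvcResult", function(object) {
  msg <- character(0)
  if (length(object@perTrialMedianRms) != 3L)
    msg <- c(msg, "exactly three trial medians are required")
  if (!isTRUE(all.equal(object@mvcValue, max(object@perTrialMedianRms))))
    msg <- c(msg, "'mvcValue' must equal the maximum trial median")
  if (!all(dim(object@plateauBounds) == c(3L, 2L)))
    msg <- c(msg, "'plateauBounds' must be a 3 x 2 matrix")
  if (length(msg)) msg else TRUE
})

#' Spearman trend of one feature against time
#'
#' @slot feature which feature the trend describes (`"rms"`, `"mdf"`,
#'   `"mnf"`).
#' @slot rho Spearman rank correlation of the feature with window time;
#'   `NA` when the feature series is constant.
#' @slot pValue two-sided p-value (large-sample t approximation).
#' @slot nWindows number of defined windows entering the correlation.
#' @export
setClass("TrendResult",
  representation(feature = "character", rho = "numeric",
                 pValue = "numeric", nWindows = "integer"))

setValidity("TrendResult", function(object) {
  msg <- character(0)
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    msg <- c(msg, "|rho| must be <= 1")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Fatigue classification from three feature trends
#'
#' Fatigue is called when RMS rises significantly with time while MDF and MNF
#' both fall significantly -- the canonical surface-EMG fatigue signature.
#' `fatigued` is `NA` ("undetermined") when any trend is undefined.
#'
#' @slot trends named list of three [TrendResult-class] objects
#'   (`rms`, `mdf`, `mnf`).
#' @slot fatigued logical flag (`NA` = undetermined).
#' @slot rule human-readable description of the decision rule applied.
#' @export
setClass("FatigueCall",
  representation(trends = "list", fatigued = "logical", rule = "character"))

setValidity("FatigueCall", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@trends)), sort(.FEATURE_NAMES)))
    msg <- c(msg, "'trends' must be a named list with elements rms, mdf, mnf")
  if (!all(vapply(object@trends, is, logical(1), "TrendResult")))
    msg <- c(msg, "all trends must be TrendResult objects")
  if (length(msg)) msg else TRUE
})

#' Agreement between two devices' fatigue trends
#'
#' Paired per-participant Spearman trend coefficients from two devices, with
#' Wilcoxon agreement tests per feature, the percentage of participants whose
#' three features have sign-concordant trends across devices, and group
#' quartile summaries.
#'
#' @slot coefA,coefB numeric matrices (participants x features) of Spearman
#'   coefficients; identical row (participant) and column (feature) order.
#' @slot tests `data.frame` with columns `feature`, `W`, `p_value`, `mode`.
#' @slot similarFraction percentage (0-100) of sign-concordant participants.
#' @slot summaryA,summaryB per-feature `data.frame`s of `median`, `q1`, `q3`.
#' @export
setClass("DeviceComparison",
  representation(coefA = "matrix", coefB = "matrix", tests = "data.frame",
                 similarFraction = "numeric",
                 summaryA = "data.frame", summaryB = "data.frame"))

setValidity("DeviceComparison", function(object) {
  msg <- character(0)
  if (!identical(dim(object@coefA), dim(object@coefB)))
    msg <- c(msg, "'coefA' and 'coefB' must have identical dimensions")
  if (!identical(rownames(object@coefA), rownames(object@coefB)))
    msg <- c(msg, "participant pairing must be preserved between devices")
  if (object@similarFraction < 0 || object@similarFraction > 100)
    msg <- c(msg, "'similarFraction' must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Synthetic-recording parameterization
#'
#' Full description of one synthetic EMG recording: amplitude (RMS) and
#' spectral-centroid trajectories over time, band-limited noise bandwidth,
#' contraction envelope (constant or cyclic squeeze/release), mains
#' contamination, optional ADC quantization and the RNG seed.
#'
#' @slot rate sampling rate, Hz.
#' @slot durationS recording length, seconds (90 s contractions by default).
#' @slot rmsTrajectory function of time (s) returning the target RMS of the
#'   active (contracted) signal.
#' @slot centroidTrajectory function of time (s) returning the target
#'   spectral centroid, Hz.
#' @slot bandwidth full bandwidth of the shaping band-pass around the
#'   centroid, Hz.
#' @slot envelope `"constant"` or `"cyclic"`.
#' @slot envelopePeriod,envelopeDuty cyclic envelope period (s) and duty
#'   fraction (squeeze on one beep, release on the next: duty 0.5).
#' @slot mainsAmp amplitude of the 60 Hz mains fundamental (harmonics decay
#'   as 1/k up to 420 Hz); 0 disables contamination.
#' @slot mainsBase mains base frequency, Hz.
#' @slot quantBits ADC bit depth to emulate, or `NA` for no quantization.
#' @slot seed integer RNG seed; generation is reproducible given the seed.
#' @export
setClass("SynthParams",
  representation(
    rate = "numeric", durationS = "numeric",
    rmsTrajectory = "function", centroidTrajectory = "function",
    bandwidth = "numeric", envelope = "character",
    envelopePeriod = "numeric", envelopeDuty = "numeric",
    mainsAmp = "numeric", mainsBase = "numeric",
    quantBits = "integer", seed = "integer"
  ))

setValidity("SynthParams", function(object) {
  msg <- character(0)
  if (object@rate <= 0) msg <- c(msg, "'rate' must be positive")
  if (object@durationS <= 0) msg <- c(msg, "'durationS' must be positive")
  if (!(object@envelope %in% c("constant", "cyclic")))
    msg <- c(msg, "'envelope' must be 'constant' or 'cyclic'")
  if (object@envelope == "cyclic" &&
      (object@envelopeDuty <= 0 || object@envelopeDuty > 1))
    msg <- c(msg, "'envelopeDuty' must lie in (0, 1]")
  if (!is.na(object@quantBits) && (object@quantBits < 2L || object@quantBits > 24L))
    msg <- c(msg, "'quantBits' must lie in [2, 24]")
  tt <- seq(0, object@durationS, length.out = 33)
  rms <- vapply(tt, object@rmsTrajectory, numeric(1))
  cen <- vapply(tt, object@centroidTrajectory, numeric(1))
  if (any(!is.finite(rms)) || any(rms <= 0))
    msg <- c(msg, "'rmsTrajectory' must be positive over [0, durationS]")
  half <- object@bandwidth / 2
  if (any(!is.finite(cen)) || any(cen - half <= 20) || any(cen + half >= 450))
    msg <- c(msg, "centroid band (centroid +/- bandwidth/2) must stay within (20, 450) Hz")
  if (length(msg)) msg else TRUE
})

#' @param rate,durationS sampling rate (Hz) and duration (s).
#' @param rmsTrajectory,centroidTrajectory functions of time in seconds (or
#'   single numbers, promoted to constant functions) giving the target RMS and
#'   spectral centroid (Hz).
#' @param bandwidth shaping band-pass full bandwidth, Hz.
#' @param envelope `"constant"` or `"cyclic"`.
#' @param envelopePeriod,envelopeDuty cyclic envelope period (s) and duty.
#' @param mainsAmp,mainsBase mains contamination amplitude and base
#'   frequency (Hz).
#' @param quantBits ADC bit depth, or `NA` to skip quantization.
#' @param seed integer RNG seed.
#' @return A [SynthParams-class] object.
#' @rdname SynthParams-class
#' @export
synthParams <- function(rate = 2000, durationS = 90,
                        rmsTrajectory = 0.5, centroidTrajectory = 100,
                        bandwidth = 80, envelope = "constant",
                        envelopePeriod = 1.0, envelopeDuty = 0.5,
                        mainsAmp = 0, mainsBase = 60,
                        quantBits = NA, seed = 1L) {
  as_fun <- function(x) if (is.function(x)) x else { v <- as.numeric(x); function(t) rep(v, length(t)) }
  new("SynthParams",
    rate = as.numeric(rate), durationS = as.numeric(durationS),
    rmsTrajectory = as_fun(rmsTrajectory),
    centroidTrajectory = as_fun(centroidTrajectory),
    bandwidth = as.numeric(bandwidth), envelope = envelope,
    envelopePeriod = as.numeric(envelopePeriod),
    envelopeDuty = as.numeric(envelopeDuty),
    mainsAmp = as.numeric(mainsAmp), mainsBase = as.numeric(mainsBase),
    quantBits = as.integer(quantBits), seed = as.integer(seed))
}
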