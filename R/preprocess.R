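#' @include AllClasses.R
NULL

# Apply one IIR filter to a sample vector, zero-phase or causal.
.apply_iir <- function(flt, x, zeroPhase) {
  if (zeroPhase) signal::filtfilt(flt, x) else
    as.numeric(signal::filter(flt, x))
}

.check_band <- function(spec, rate) {
  if (spec@bandHigh >= rate / 2)
    stop("upper band edge (", spec@bandHigh,
         " Hz) must be below the Nyquist frequency (", rate / 2, " Hz)")
}

#' Butterworth band-pass filter
#'
#' The standard surface-EMG band of 20-450 Hz with a 4th-order Butterworth
#' prototype, by default applied forward-backward (zero phase) so that
#' downstream window timestamps carry no group delay. Edge transients are
#' flagged, not removed: the returned recording carries an attribute
#' `transient_s` (0.25 s) that windowing code may use to skip the first and
#' last stretch.
#'
#' @param recording a [Recording-class].
#' @param spec a [FilterSpec-class]; defaults give the 20-450 Hz band.
#' @return The filtered [Recording-class] (same length, rate and metadata).
#' @examples
#' rec <- Recording(sin(2 * pi * 100 * seq(0, 2, by = 1 / 2000)))
#' filt <- bandpass(rec)
#' @export
bandpass <- function(recording, spec = filterSpec()) {
  .check_band(spec, recording@rate)
  if (length(recording@samples) == 0) stop("empty recording")
  w <- c(spec@bandLow, spec@bandHigh) / (recording@rate / 2)
  flt <- signal::butter(spec@order, w, type = "pass")
  out <- recording
  out@samples <- .apply_iir(flt, recording@samples, spec@zeroPhase)
  attr(out@samples, "transient_s") <- 0.25
  out
}

#' Mains comb-notch filter
#'
#' A cascade of second-order Butterworth band-stop sections, one at each
#' harmonic of the mains base frequency below the upper band edge (60, 120,
#' ..., 420 Hz at defaults). Section bandwidth is `f0 / Q`.
#'
#' @inheritParams bandpass
#' @return The filtered [Recording-class].
#' @export
notchComb <- function(recording, spec = filterSpec()) {
  .check_band(spec, recording@rate)
  if (length(recording@samples) == 0) stop("empty recording")
  x <- recording@samples
  harmonics <- seq(spec@notchBase, spec@bandHigh - 1e-9, by = spec@notchBase)
  for (f0 in harmonics) {
    bw <- f0 / spec@notchQ
    w <- c(f0 - bw / 2, f0 + bw / 2) / (recording@rate / 2)
    flt <- signal::butter(1, w, type = "stop")
    x <- .apply_iir(flt, x, spec@zeroPhase)
  }
  out <- recording
  out@samples <- x
  out
}

#' Full preprocessing chain
#'
#' Band-pass followed by the mains notch comb -- the filtering applied to
#' every recording before feature extraction.
#'
#' @inheritParams bandpass
#' @return The filtered [Recording-class].
#' @export
preprocessRecording <- function(recording, spec = filterSpec()) {
  notchComb(bandpass(recording, spec), spec)
}

#' Emulate ADC quantization
#'
#' Maps samples onto a uniform grid of exactly `2^bits` levels spanning
#' `[-full_scale, +full_scale]`; values outside the range clip. Used to study
#' the effect of converter resolution (a 10-bit ADC resolves 1024 levels, a
#' 14-bit one 16384) on the extracted features.
#'
#' @param recording a [Recording-class].
#' @param bits integer bit depth in `[2, 24]`.
#' @param full_scale positive full-scale amplitude; defaults to the
#'   recording's absolute maximum.
#' @return The quantized [Recording-class].
#' @export
quantize <- function(recording, bits, full_scale = max(abs(samples(recording)))) {
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 2L || bits > 24L)
    stop("'bits' must be an integer in [2, 24]")
  if (!is.finite(full_scale) || full_scale <= 0)
    stop("'full_scale' must be positive")
  nlev <- 2^bits
  step <- 2 * full_scale / (nlev - 1)
  idx <- round((recording@samples + full_scale) / step)
  idx <- pmax(pmin(idx, nlev - 1), 0)
  out <- recording
  out@samples <- idx * step - full_scale
  out
}
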