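#' @include AllClasses.R utils.R
NULL

# Butterworth-magnitude band centered at f0 with full width bw, symmetric in
# frequency so the programmed centroid equals the spectral mean exactly.
# Order 8 keeps the band near-rectangular: skirt power outside the band is
# negligible, so the programmed RMS survives the analysis filter chain.
.band_mag <- function(f, f0, bw, order = 8) {
  1 / sqrt(1 + ((f - f0) / (bw / 2))^(2 * order))
}

#' Generate a synthetic EMG recording
#'
#' Band-limited Gaussian noise synthesized frame-by-frame in the frequency
#' domain: each Hann-windowed frame of white noise is shaped by a
#' Butterworth-magnitude band centered at `centroidTrajectory(t)` with the
#' given bandwidth, normalized to unit RMS, and overlap-added (75% overlap,
#' for which squared Hann windows sum to a constant). The result is scaled so
#' the windowed RMS tracks `rmsTrajectory(t)`, multiplied by the contraction
#' envelope (constant, or a cyclic squeeze/release square wave emulating
#' beep-paced isotonic contractions), contaminated with a mains tone plus
#' 1/k-weighted harmonics up to 420 Hz, and optionally quantized to an ADC
#' grid. Generation is exactly reproducible for a fixed seed and leaves the
#' caller's RNG state untouched.
#'
#' This is a phenomenological generator: it gives RMS, MDF and MNF their
#' programmed trajectories but does not model motor-unit physiology.
#'
#' @param params a [SynthParams-class].
#' @param phase phase label for the returned [Recording-class].
#' @param participantId participant identifier.
#' @return A [Recording-class] in raw units.
#' @examples
#' p <- synthParams(durationS = 5, rmsTrajectory = 0.5,
#'                  centroidTrajectory = 100, seed = 7L)
#' rec <- generateEmg(p)
#' @export
generateEmg <- function(params, phase = "isometric",
                        participantId = NA_character_) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  rate <- params@rate
  n <- as.integer(round(params@durationS * rate))
  L <- as.integer(round(0.25 * rate))
  if (L %% 4L != 0L) L <- L + (4L - L %% 4L)
  H <- L %/% 4L
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / L))  # periodic Hann
  fgrid <- pmin(0:(L - 1L), L - (0:(L - 1L))) * rate / L

  .with_seed(params@seed, {
    # pad one frame on both sides so every kept sample has full Hann coverage
    npad <- n + 2L * L
    acc <- numeric(npad)
    wsq <- numeric(npad)
    starts <- seq(1L, npad - L + 1L, by = H)
    for (s in starts) {
      tc <- ((s - 1L) - L + L / 2) / rate
      f0 <- params@centroidTrajectory(min(max(tc, 0), params@durationS))
      mag <- .band_mag(fgrid, f0, params@bandwidth)
      e <- stats::rnorm(L)
      y <- Re(stats::fft(stats::fft(e) * mag, inverse = TRUE)) / L
      y <- y / sqrt(mean(y^2))
      idx <- s:(s + L - 1L)
      acc[idx] <- acc[idx] + y * w
      wsq[idx] <- wsq[idx] + w^2
    }
    keep <- (L + 1L):(L + n)
    x <- acc[keep] / sqrt(wsq[keep])
    # constrained realization: normalize exact RMS per non-overlapping 50 ms
    # block, so any analysis window (a multiple of 50 ms) has unit RMS and
    # the windowed amplitude tracks the programmed trajectory exactly
    B <- as.integer(round(0.05 * rate))
    nb <- ceiling(n / B)
    blk <- rep(seq_len(nb), each = B)[seq_len(n)]
    brms <- sqrt(as.numeric(tapply(x^2, blk, mean)))
    x <- x / pmax(brms[blk], 1e-12)

    tt <- (seq_len(n) - 1L) / rate
    x <- x * params@rmsTrajectory(tt)
    if (params@envelope == "cyclic") {
      on <- (tt %% params@envelopePeriod) <
        params@envelopeDuty * params@envelopePeriod
      x <- x * as.numeric(on)
    }
    if (params@mainsAmp > 0) {
      kmax <- max(1L, floor(420 / params@mainsBase))
      for (k in seq_len(kmax)) {
        phi <- stats::runif(1, 0, 2 * pi)
        x <- x + (params@mainsAmp / k) * sin(2 * pi * k * params@mainsBase * tt + phi)
      }
    }
    rec <- Recording(x, rate = rate, phase = phase,
                     participantId = participantId, units = "raw")
    if (!is.na(params@quantBits)) rec <- quantize(rec, params@quantBits)
    rec
  })
}

#' Preset: fatiguing isometric contraction
#'
#' The canonical fatigue pattern over a 90 s isometric hold at 50% MVC:
#' RMS rising linearly from 0.5 to 0.8 of a nominal unit MVC (progressive
#' motor-unit recruitment) while the spectral centroid falls linearly from
#' 120 to 80 Hz (spectral compression from conduction-velocity slowing).
#'
#' @param seed integer RNG seed.
#' @param durationS contraction length, seconds.
#' @param mainsAmp optional mains contamination amplitude.
#' @param quantBits optional ADC bit depth.
#' @return A [Recording-class]; the matching nominal MVC amplitude is 1, so
#'   features can be normalized with `mvc = 1`.
#' @export
generateFatiguingIsometric <- function(seed = 1L, durationS = 90,
                                       mainsAmp = 0, quantBits = NA) {
  d <- durationS
  p <- synthParams(
    durationS = d,
    rmsTrajectory = function(t) 0.5 + 0.3 * pmin(t, d) / d,
    centroidTrajectory = function(t) 120 - 40 * pmin(t, d) / d,
    bandwidth = 80, envelope = "constant",
    mainsAmp = mainsAmp, quantBits = quantBits, seed = seed)
  generateEmg(p, phase = "isometric")
}

#' Preset: stationary (non-fatiguing) contraction
#'
#' Constant RMS and spectral centroid -- a hold that produces no fatigue
#' signature.
#'
#' @inheritParams generateFatiguingIsometric
#' @param rms,centroid constant trajectory values.
#' @param envelope `"constant"` or `"cyclic"` (1 Hz squeeze/release).
#' @return A [Recording-class].
#' @export
generateStationary <- function(seed = 1L, durationS = 90, rms = 0.5,
                               centroid = 100, envelope = "constant",
                               mainsAmp = 0, quantBits = NA) {
  p <- synthParams(durationS = durationS, rmsTrajectory = rms,
                   centroidTrajectory = centroid, bandwidth = 80,
                   envelope = envelope, mainsAmp = mainsAmp,
                   quantBits = quantBits, seed = seed)
  generateEmg(p, phase = if (envelope == "cyclic") "isotonic" else "isometric")
}

#' Preset: fatiguing isotonic (cyclic) contraction
#'
#' Beep-paced squeeze/release cycles (1 s period, duty 0.5) with the same
#' fatigue trajectories as the isometric preset.
#'
#' @inheritParams generateFatiguingIsometric
#' @return A [Recording-class] with phase `"isotonic"`.
#' @export
generateFatiguingIsotonic <- function(seed = 1L, durationS = 90,
                                      mainsAmp = 0, quantBits = NA) {
  d <- durationS
  p <- synthParams(
    durationS = d,
    rmsTrajectory = function(t) 0.5 + 0.3 * pmin(t, d) / d,
    centroidTrajectory = function(t) 120 - 40 * pmin(t, d) / d,
    bandwidth = 80, envelope = "cyclic", envelopePeriod = 1, envelopeDuty = 0.5,
    mainsAmp = mainsAmp, quantBits = quantBits, seed = seed)
  generateEmg(p, phase = "isotonic")
}

#' Generate three maximal-voluntary-contraction trials
#'
#' Each 8 s trial ramps up over 1 s, holds a plateau for 6 s at its level and
#' drops over the final second. The trial band (65-115 Hz) sits between the
#' mains-notch harmonics so the programmed amplitude survives the filter
#' chain and [computeMvc()] recovers `max(levels)` to within a few percent.
#'
#' @param levels three positive plateau RMS levels.
#' @param seed integer RNG seed.
#' @return List of three [Recording-class] objects with phase `"mvc"`.
#' @export
generateMvcTrials <- function(levels = c(1, 1, 1), seed = 1L) {
  if (length(levels) != 3L || any(levels <= 0))
    stop("'levels' must be three positive plateau levels")
  lapply(1:3, function(i) {
    lv <- levels[i]
    traj <- function(t) {
      amp <- ifelse(t < 1, pmax(t, 0.02),
                    ifelse(t <= 7, 1, pmax(8 - t, 0.02)))
      lv * amp
    }
    p <- synthParams(durationS = 8, rmsTrajectory = traj,
                     centroidTrajectory = 90, bandwidth = 50,
                     envelope = "constant", seed = seed + i)
    generateEmg(p, phase = "mvc")
  })
}
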