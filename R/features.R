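#' @include AllClasses.R
NULL

#' One-sided power spectrum of a signal window
#'
#' The window mean is removed before the FFT; power is normalized so that
#' `sum(power)` equals the mean square of the demeaned window (Parseval),
#' which makes MDF/MNF independent of window length conventions. No
#' averaging or tapering is applied (plain per-window FFT); tapering happens
#' only inside the short-time transform.
#'
#' @param window_samples numeric vector (at least 16 samples).
#' @param rate sampling rate, Hz.
#' @return An [EmgSpectrum-class]. A constant (zero-power) window yields an
#'   all-zero spectrum, which downstream feature calls treat as undefined.
#' @export
periodogram <- function(window_samples, rate) {
  n <- length(window_samples)
  if (n < 16L) stop("need at least 16 samples, got ", n)
  xd <- window_samples - mean(window_samples)
  X <- stats::fft(xd)
  p_full <- Mod(X)^2 / n^2
  nh <- n %/% 2L
  keep <- seq_len(nh + 1L)            # DC .. Nyquist (or highest bin, odd n)
  power <- p_full[keep]
  # fold negative frequencies onto their positive mirrors
  mirrored <- 2:(if (n %% 2L == 0L) nh else nh + 1L)
  power[mirrored] <- 2 * power[mirrored]
  new("EmgSpectrum", freqs = (keep - 1L) * rate / n, power = power)
}

.total_power <- function(spectrum) sum(spectrum@power)

#' Median power frequency
#'
#' The frequency at which cumulative spectral power first reaches half of the
#' total. With `interpolate = TRUE` (default) the half-power crossing is
#' located by linear interpolation between the bracketing bins; a crossing
#' whose preceding cumulative power is zero (power concentrated in a single
#' leading bin) returns that bin's frequency exactly. `interpolate = FALSE`
#' gives the discrete first-bin-at-or-above-half convention.
#'
#' @param spectrum an [EmgSpectrum-class] with positive total power.
#' @param interpolate logical; see above.
#' @return Frequency in Hz.
#' @export
mdf <- function(spectrum, interpolate = TRUE) {
  p <- spectrum@power
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0)
    stop("median frequency is undefined for a zero-power spectrum")
  half <- tot / 2
  cum <- cumsum(p)
  k <- which(cum >= half - 1e-12 * tot)[1]
  if (!interpolate || k == 1L || cum[k - 1L] <= 0)
    return(spectrum@freqs[k])
  f0 <- spectrum@freqs[k - 1L]; f1 <- spectrum@freqs[k]
  c0 <- cum[k - 1L]; c1 <- cum[k]
  f0 + (half - c0) / (c1 - c0) * (f1 - f0)
}

#' Mean power frequency (spectral centroid)
#'
#' @inheritParams mdf
#' @return Power-weighted mean frequency, Hz.
#' @export
mnf <- function(spectrum) {
  tot <- sum(spectrum@power)
  if (!is.finite(tot) || tot <= 0)
    stop("mean frequency is undefined for a zero-power spectrum")
  sum(spectrum@freqs * spectrum@power) / tot
}

# Column-wise window split; trailing partial window dropped.
.window_matrix <- function(x, wlen) {
  nwin <- length(x) %/% wlen
  matrix(x[seq_len(nwin * wlen)], nrow = wlen)
}

#' Per-window features for isometric contractions
#'
#' RMS (normalized to %MVC when an MVC is given), MDF and MNF over
#' consecutive non-overlapping windows (one second by default) of a filtered
#' recording. Windows with zero spectral power are flagged as undefined
#' rather than silently dropped.
#'
#' @param recording a (filtered) [Recording-class].
#' @param mvc an [MvcResult-class], a positive MVC amplitude, or `NA` to
#'   leave RMS un-normalized.
#' @param window_s analysis window, seconds.
#' @return A [FeatureSeries-class] of kind `"isometric"`.
#' @export
isometricFeatures <- function(recording, mvc = NA, window_s = 1.0) {
  wlen <- as.integer(round(window_s * recording@rate))
  if (length(recording@samples) < wlen)
    stop("recording shorter than one analysis window")
  m <- .window_matrix(recording@samples, wlen)
  nwin <- ncol(m)
  rms <- sqrt(colMeans(m^2))
  mdf_v <- mnf_v <- rep(NA_real_, nwin)
  defined <- rep(TRUE, nwin)
  for (i in seq_len(nwin)) {
    sp <- periodogram(m[, i], recording@rate)
    if (.total_power(sp) <= 0) { defined[i] <- FALSE; next }
    mdf_v[i] <- mdf(sp)
    mnf_v[i] <- mnf(sp)
  }
  if (!is(mvc, "MvcResult") && length(mvc) == 1 && is.na(mvc)) {
    rms_out <- rms
  } else {
    rms_out <- normalizeToMvc(rms, mvc)
  }
  new("FeatureSeries",
      windowStart = (seq_len(nwin) - 1L) * wlen / recording@rate,
      rms = rms_out, mdf = mdf_v, mnf = mnf_v, defined = defined,
      kind = "isometric")
}

#' Instantaneous median / mean frequencies via the short-time Fourier
#' transform
#'
#' Hann-windowed STFT frames; each frame's one-sided power spectrum feeds the
#' same MDF/MNF definitions used per-window, giving instantaneous series
#' (IMDF, IMNF) suited to non-stationary (isotonic) contractions. Frames
#' whose mean-square amplitude is below `silence_rel` times the loudest
#' frame's (relaxation gaps, dead signal) are flagged undefined.
#'
#' @param recording a (filtered) [Recording-class].
#' @param stft_window_s STFT frame length, seconds (0.25 s default: 2 Hz
#'   resolution at the cost of 0.25 s time smearing).
#' @param hop_s frame hop, seconds (0.025 s default: 40 frames per second).
#' @param silence_rel relative mean-square threshold flagging silent frames.
#' @return `data.frame` with columns `frame_time_s` (frame start),
#'   `imdf`, `imnf`, `defined`.
#' @export
stftInstFreqs <- function(recording, stft_window_s = 0.25, hop_s = 0.025,
                          silence_rel = 1e-6) {
  rate <- recording@rate
  L <- as.integer(round(stft_window_s * rate))
  H <- max(1L, as.integer(round(hop_s * rate)))
  x <- recording@samples
  if (length(x) < L) stop("recording shorter than one STFT frame")
  starts <- seq(1L, length(x) - L + 1L, by = H)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)))  # Hann
  ms <- vapply(starts, function(s) mean(x[s:(s + L - 1L)]^2), numeric(1))
  thr <- silence_rel * max(ms)
  imdf <- imnf <- rep(NA_real_, length(starts))
  defined <- ms > thr & ms > 0
  for (i in seq_along(starts)) {
    if (!defined[i]) next
    frame <- x[starts[i]:(starts[i] + L - 1L)] * w
    sp <- periodogram(frame, rate)
    if (.total_power(sp) <= 0) { defined[i] <- FALSE; next }
    imdf[i] <- mdf(sp)
    imnf[i] <- mnf(sp)
  }
  data.frame(frame_time_s = (starts - 1L) / rate,
             imdf = imdf, imnf = imnf, defined = defined)
}

#' Centered moving-average smoothing
#'
#' Averages `n` consecutive values around each position (window truncated at
#' the series edges); `NA` (flagged) values are excluded from each average,
#' and positions whose window holds no defined value stay `NA`. Output length
#' equals input length.
#'
#' @param x numeric vector, possibly with `NA`s.
#' @param n window size in series samples (100 by default, approximately
#'   2.5 s of STFT frames at the default hop).
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smoothSeries <- function(x, n = 100) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  N <- length(x)
  if (N == 0L || n == 1L) return(x)
  lo <- (n - 1L) %/% 2L
  hi <- n - 1L - lo
  ok <- !is.na(x)
  vals <- ifelse(ok, x, 0)
  csum <- c(0, cumsum(vals))
  ccnt <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(N)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, N)
  s <- csum[b + 1L] - csum[a]
  k <- ccnt[b + 1L] - ccnt[a]
  out <- ifelse(k > 0, s / k, NA_real_)
  out
}

#' Per-second averaged features for isotonic contractions
#'
#' The strategy for cyclic squeeze/release contractions: instantaneous
#' frequencies from the short-time transform, smoothed with a 100-frame
#' moving average, then averaged over non-overlapping one-second windows.
#' RMS is computed per full second of the signal (relaxation gaps included)
#' and normalized to %MVC.
#'
#' @inheritParams isometricFeatures
#' @param stft_window_s,hop_s,smooth_n short-time transform parameters, see
#'   [stftInstFreqs()] and [smoothSeries()].
#' @param rms_burst_only if `TRUE`, per-second RMS is computed over the
#'   active (non-silent) portion only; default `FALSE` uses the full second.
#' @return A [FeatureSeries-class] of kind `"isotonic_averaged"`; seconds
#'   with no defined frame are flagged.
#' @export
isotonicFeatures <- function(recording, mvc = NA, window_s = 1.0,
                             stft_window_s = 0.25, hop_s = 0.025,
                             smooth_n = 100, rms_burst_only = FALSE) {
  inst <- stftInstFreqs(recording, stft_window_s, hop_s)
  sm_imdf <- smoothSeries(ifelse(inst$defined, inst$imdf, NA_real_), smooth_n)
  sm_imnf <- smoothSeries(ifelse(inst$defined, inst$imnf, NA_real_), smooth_n)

  nsec <- floor(recordingDuration(recording) / window_s)
  if (nsec < 1) stop("recording shorter than one averaging window")
  sec_of_frame <- floor(inst$frame_time_s / window_s)

  wlen <- as.integer(round(window_s * recording@rate))
  m <- .window_matrix(recording@samples, wlen)[, seq_len(nsec), drop = FALSE]
  if (rms_burst_only) {
    rms <- apply(m, 2, function(col) {
      thr <- 1e-3 * max(abs(col))
      act <- col[abs(col) > thr]
      if (length(act)) sqrt(mean(act^2)) else 0
    })
  } else {
    rms <- sqrt(colMeans(m^2))
  }

  mdf_v <- mnf_v <- rep(NA_real_, nsec)
  defined <- rep(FALSE, nsec)
  for (s in seq_len(nsec)) {
    in_sec <- sec_of_frame == (s - 1L) & !is.na(sm_imdf)
    if (any(in_sec)) {
      mdf_v[s] <- mean(sm_imdf[in_sec])
      mnf_v[s] <- mean(sm_imnf[in_sec])
      defined[s] <- TRUE
    }
  }
  rms_out <- if (!is(mvc, "MvcResult") && length(mvc) == 1 && is.na(mvc)) rms
             else normalizeToMvc(rms, mvc)
  new("FeatureSeries",
      windowStart = (seq_len(nsec) - 1L) * window_s,
      rms = rms_out, mdf = mdf_v, mnf = mnf_v, defined = defined,
      kind = "isotonic_averaged")
}
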