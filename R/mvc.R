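#' @include AllClasses.R
NULL

#' Windowed RMS envelope
#'
#' Root-mean-square amplitude over consecutive non-overlapping windows
#' (100 ms by default, the convention for MVC trials). The trailing partial
#' window is dropped.
#'
#' @param recording a [Recording-class].
#' @param window_s window length in seconds.
#' @return `data.frame` with columns `window_start_s` and `rms`.
#' @export
rmsEnvelope <- function(recording, window_s = 0.1) {
  n <- length(recording@samples)
  wlen <- as.integer(round(window_s * recording@rate))
  if (wlen < 1L) stop("'window_s' is shorter than one sample")
  if (n < wlen) stop("recording shorter than one window (",
                     window_s, " s at ", recording@rate, " Hz)")
  nwin <- n %/% wlen
  m <- matrix(recording@samples[seq_len(nwin * wlen)], nrow = wlen)
  data.frame(
    window_start_s = (seq_len(nwin) - 1L) * wlen / recording@rate,
    rms = sqrt(colMeans(m^2)))
}

#' Locate the contraction plateau of an MVC trial
#'
#' Automates the crop of the force plateau between the initial ramp and the
#' final drop: the longest contiguous run of envelope windows whose RMS is at
#' least `threshold_frac` of the envelope maximum (first such run on ties).
#'
#' @param envelope `data.frame` from [rmsEnvelope()].
#' @param threshold_frac fraction of the peak envelope RMS (default 0.8).
#' @return List with `start_s`, `end_s` (half-open interval) and the window
#'   `indices` of the plateau.
#' @export
cropPlateau <- function(envelope, threshold_frac = 0.8) {
  rms <- envelope$rms
  if (length(rms) < 5L) stop("envelope must contain at least 5 windows")
  peak <- max(rms)
  if (!is.finite(peak) || peak <= 0)
    stop("degenerate trial: envelope never rises above zero")
  above <- rms >= threshold_frac * peak
  if (!any(above)) stop("degenerate trial: no window reaches the threshold")
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  idx <- seq(starts[best], ends[best])
  wlen_s <- if (length(rms) > 1)
    envelope$window_start_s[2] - envelope$window_start_s[1]
  else envelope$window_start_s[1] + 1  # single window: nominal length unknown
  list(start_s = envelope$window_start_s[idx[1]],
       end_s = envelope$window_start_s[idx[length(idx)]] + wlen_s,
       indices = idx)
}

#' Estimate the maximal voluntary contraction from three trials
#'
#' Per trial: filter (same chain as the contraction recordings), 100 ms RMS
#' envelope, automatic plateau crop, median of the plateau-window RMS values.
#' The MVC is the maximum of the three trial medians.
#'
#' @param recordings list of exactly three MVC-phase [Recording-class]
#'   objects.
#' @param window_s envelope window, seconds.
#' @param threshold_frac plateau threshold as in [cropPlateau()].
#' @param spec [FilterSpec-class] for preprocessing; `NULL` skips filtering.
#' @return An [MvcResult-class].
#' @export
computeMvc <- function(recordings, window_s = 0.1, threshold_frac = 0.8,
                       spec = filterSpec()) {
  if (length(recordings) != 3L)
    stop("exactly three MVC trials are required, got ", length(recordings))
  medians <- numeric(3)
  bounds <- matrix(NA_real_, 3, 2, dimnames = list(NULL, c("start_s", "end_s")))
  for (i in 1:3) {
    rec <- recordings[[i]]
    if (!is.null(spec)) rec <- preprocessRecording(rec, spec)
    env <- rmsEnvelope(rec, window_s)
    pl <- cropPlateau(env, threshold_frac)
    medians[i] <- stats::median(env$rms[pl$indices])
    bounds[i, ] <- c(pl$start_s, pl$end_s)
  }
  new("MvcResult", perTrialMedianRms = medians, mvcValue = max(medians),
      plateauBounds = bounds)
}

#' Normalize an amplitude to percent MVC
#'
#' @param value RMS amplitude(s) in the same units as the MVC trials.
#' @param mvc an [MvcResult-class] or a positive MVC amplitude.
#' @return `100 * value / mvc`, in %MVC.
#' @export
normalizeToMvc <- function(value, mvc) {
  m <- if (is(mvc, "MvcResult")) mvc@mvcValue else as.numeric(mvc)
  if (!is.finite(m) || m <= 0) stop("MVC value must be positive")
  100 * value / m
}
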