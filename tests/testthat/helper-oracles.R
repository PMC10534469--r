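# Brute-force / independent oracles used across the suite. These deliberately
# avoid the package's vectorized code paths: plain loops and first-principles
# formulas only.

# Median frequency: explicit loop over the cumulative power, interpolating at
# the half-power crossing (crossings whose preceding cumulative mass is zero
# return the bin frequency itself).
brute_mdf <- function(freqs, power) {
  tot <- 0
  for (p in power) tot <- tot + p
  half <- tot / 2
  cum <- 0
  for (k in seq_along(power)) {
    prev <- cum
    cum <- cum + power[k]
    if (cum >= half - 1e-12 * tot) {
      if (k == 1 || prev <= 0) return(freqs[k])
      return(freqs[k - 1] + (half - prev) / (cum - prev) *
               (freqs[k] - freqs[k - 1]))
    }
  }
  stop("no crossing found")
}

# Median frequency via a 10x finer grid scan over the linearly interpolated
# cumulative distribution (coarser agreement: within one fine-grid step).
brute_mdf_grid <- function(freqs, power, refine = 10) {
  cum <- cumsum(power)
  tot <- cum[length(cum)]
  grid <- seq(freqs[1], freqs[length(freqs)],
              length.out = refine * length(freqs))
  cg <- stats::approx(freqs, cum, xout = grid, rule = 2)$y
  grid[which(cg >= tot / 2)[1]]
}

# Spectral centroid by explicit summation.
brute_mnf <- function(freqs, power) {
  num <- 0; den <- 0
  for (k in seq_along(power)) {
    num <- num + freqs[k] * power[k]
    den <- den + power[k]
  }
  num / den
}

# Centered moving average with NA exclusion, double loop.
brute_moving_avg <- function(x, n) {
  N <- length(x)
  lo <- (n - 1) %/% 2
  hi <- n - 1 - lo
  out <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    s <- 0; k <- 0
    for (j in max(1, i - lo):min(N, i + hi)) {
      if (!is.na(x[j])) { s <- s + x[j]; k <- k + 1 }
    }
    if (k > 0) out[i] <- s / k
  }
  out
}

# Average ranks from first principles, then Pearson correlation on the ranks.
brute_spearman <- function(x, y) {
  avrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avrank(x); ry <- avrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact Wilcoxon signed-rank by full enumeration of all 2^n sign patterns.
enum_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  pl <- mean(v_all <= v_obs)
  pu <- mean(v_all >= v_obs)
  list(V = v_obs, p = min(1, 2 * min(pl, pu)))
}

# Linear-interpolation (type 7) quantile from a hand sort.
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (ifelse(lo + 2 <= length(x), x[lo + 2], x[lo + 1]) -
                            x[lo + 1])
}

# All contiguous runs above a threshold, longest first-on-tie.
brute_longest_run <- function(rms, frac) {
  thr <- frac * max(rms)
  best <- integer(0)
  i <- 1
  while (i <= length(rms)) {
    if (rms[i] >= thr) {
      j <- i
      while (j < length(rms) && rms[j + 1] >= thr) j <- j + 1
      if (j - i + 1 > length(best)) best <- i:j
      i <- j + 1
    } else i <- i + 1
  }
  best
}

# Magnitude of a designed digital filter at frequency f (Hz), evaluated
# directly from the transfer-function polynomials.
filter_mag <- function(flt, f, rate) {
  z <- exp(-1i * 2 * pi * f / rate)
  Mod(sum(flt$b * z^(0:(length(flt$b) - 1))) /
        sum(flt$a * z^(0:(length(flt$a) - 1))))
}

bandpass_mag <- function(f, rate = 2000, low = 20, high = 450, order = 4) {
  filter_mag(signal::butter(order, c(low, high) / (rate / 2), type = "pass"),
             f, rate)
}

# Steady-state amplitude of a (near-)sinusoidal signal from its mid-section
# RMS over an integer number of cycles.
tone_amplitude <- function(y, rate, f) {
  cycles <- floor(1 * f)                       # 1 s worth of whole cycles
  len <- round(cycles * rate / f)
  mid <- floor(length(y) / 2)
  seg <- y[(mid - len %/% 2):(mid - len %/% 2 + len - 1)]
  sqrt(2 * mean(seg^2))
}

make_tone <- function(f, duration_s = 2, rate = 2000, amp = 1,
                      phase = "isometric") {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  Recording(amp * sin(2 * pi * f * t), rate = rate, phase = phase)
}
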