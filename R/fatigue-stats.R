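#' @include AllClasses.R
NULL

#' Spearman trend of one feature against time
#'
#' Rank correlation between window time (equivalently window index; ties in
#' time cannot occur) and a feature, with average ranks for tied feature
#' values and the large-sample t approximation for the p-value. Undefined
#' (`NA`) windows are excluded; at least five defined windows are required.
#'
#' @param series a [FeatureSeries-class] or a plain numeric vector ordered
#'   in time.
#' @param feature which feature to test: `"rms"`, `"mdf"` or `"mnf"`
#'   (ignored when `series` is a bare vector).
#' @return A [TrendResult-class]; a constant series yields `rho = NA`
#'   (flagged, not an error).
#' @export
spearmanTrend <- function(series, feature = c("rms", "mdf", "mnf")) {
  feature <- match.arg(feature)
  if (is(series, "FeatureSeries")) {
    y <- slot(series, feature)
    t_idx <- seq_along(y)
    keep <- series@defined & !is.na(y)
  } else {
    y <- as.numeric(series)
    t_idx <- seq_along(y)
    keep <- !is.na(y)
  }
  y <- y[keep]; t_idx <- t_idx[keep]
  n <- length(y)
  if (n < 5L) stop("need at least 5 defined windows, got ", n)
  if (length(unique(y)) == 1L)
    return(new("TrendResult", feature = feature, rho = NA_real_,
               pValue = NA_real_, nWindows = n))
  ct <- suppressWarnings(
    stats::cor.test(t_idx, y, method = "spearman", exact = FALSE))
  new("TrendResult", feature = feature, rho = unname(ct$estimate),
      pValue = ct$p.value, nWindows = n)
}

#' Compute all three feature trends of a series
#'
#' @param series a [FeatureSeries-class].
#' @return Named list of [TrendResult-class] (`rms`, `mdf`, `mnf`).
#' @export
featureTrends <- function(series) {
  list(rms = spearmanTrend(series, "rms"),
       mdf = spearmanTrend(series, "mdf"),
       mnf = spearmanTrend(series, "mnf"))
}

#' Classify muscle fatigue from three feature trends
#'
#' The fatigue signature: RMS rises with time (motor-unit recruitment) while
#' both spectral frequencies fall (conduction-velocity slowing). Fatigue is
#' called when the RMS trend is significantly positive and the MDF and MNF
#' trends significantly negative, each with `|rho| >= rho_min` and
#' `p < alpha`. No multiple-testing correction is applied across the three
#' features. Any undefined trend gives an undetermined (`NA`) call, distinct
#' from "not fatigued".
#'
#' @param trends named list of [TrendResult-class] (`rms`, `mdf`, `mnf`),
#'   e.g. from [featureTrends()], or a [FeatureSeries-class].
#' @param alpha significance threshold (0.05).
#' @param rho_min minimum trend magnitude (0.3) guarding against calling
#'   trivially weak but significant trends.
#' @return A [FatigueCall-class].
#' @export
classifyFatigue <- function(trends, alpha = 0.05, rho_min = 0.3) {
  if (is(trends, "FeatureSeries")) trends <- featureTrends(trends)
  stopifnot(all(c("rms", "mdf", "mnf") %in% names(trends)))
  rho <- vapply(trends, slot, numeric(1), "rho")
  p <- vapply(trends, slot, numeric(1), "pValue")
  fatigued <- if (any(is.na(rho)) || any(is.na(p))) NA else
    (rho[["rms"]] >= rho_min && p[["rms"]] < alpha) &&
    (rho[["mdf"]] <= -rho_min && p[["mdf"]] < alpha) &&
    (rho[["mnf"]] <= -rho_min && p[["mnf"]] < alpha)
  rule <- sprintf(
    "rms: rho >= %g & p < %g; mdf, mnf: rho <= -%g & p < %g",
    rho_min, alpha, rho_min, alpha)
  new("FatigueCall", trends = trends[c("rms", "mdf", "mnf")],
      fatigued = fatigued, rule = rule)
}

.coef_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  x
}

#' Percentage of participants with sign-concordant trend profiles
#'
#' A participant counts as "similar" across devices when all features have
#' trend coefficients of matching sign on both devices.
#'
#' @param coefA,coefB numeric matrices (participants x features) of Spearman
#'   coefficients, same participants in the same order (row names are
#'   matched when present).
#' @return Percentage in `[0, 100]`.
#' @export
signAgreement <- function(coefA, coefB) {
  A <- .coef_matrix(coefA); B <- .coef_matrix(coefB)
  if (!identical(dim(A), dim(B)))
    stop("devices report different numbers of participants or features")
  if (!identical(rownames(A), rownames(B)))
    stop("participant sets differ between devices: ",
         paste(union(setdiff(rownames(A), rownames(B)),
                     setdiff(rownames(B), rownames(A))), collapse = ", "))
  similar <- rowSums(sign(A) == sign(B)) == ncol(A)
  100 * sum(similar) / nrow(A)
}

#' Wilcoxon agreement test between two devices' trend coefficients
#'
#' Compares paired per-participant Spearman coefficients from two devices.
#' `mode = "signed_rank"` (default, appropriate for participant-paired data)
#' runs the paired Wilcoxon signed-rank test with zero differences dropped;
#' `mode = "rank_sum"` the two-sample rank-sum test on the pooled vectors.
#' The exact small-sample distribution is used for n <= 25 without ties;
#' larger samples or ties use the normal approximation with tie correction.
#' Identical vectors (all differences zero) are degenerate and reported as
#' no evidence of a difference with `p = 1` by convention.
#'
#' @param coeffsA,coeffsB numeric vectors of per-participant coefficients,
#'   paired by position.
#' @param mode `"signed_rank"` or `"rank_sum"`.
#' @return List with `W`, `p_value`, `mode` and `n`.
#' @export
deviceAgreementTest <- function(coeffsA, coeffsB,
                                mode = c("signed_rank", "rank_sum")) {
  mode <- match.arg(mode)
  n <- length(coeffsA)
  if (length(coeffsB) != n) stop("coefficient vectors must be paired")
  if (n < 5L) stop("need at least 5 paired coefficients, got ", n)
  if (mode == "signed_rank") {
    d <- coeffsA - coeffsB
    if (all(d == 0))
      return(list(W = 0, p_value = 1, mode = mode, n = n,
                  note = "all differences zero: no evidence of difference"))
    nz <- d[d != 0]
    exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
    ht <- suppressWarnings(
      stats::wilcox.test(coeffsA, coeffsB, paired = TRUE, exact = exact,
                         correct = TRUE))
  } else {
    exact <- n <= 25L && !any(duplicated(c(coeffsA, coeffsB)))
    ht <- suppressWarnings(
      stats::wilcox.test(coeffsA, coeffsB, paired = FALSE, exact = exact,
                         correct = TRUE))
  }
  list(W = unname(ht$statistic), p_value = ht$p.value, mode = mode, n = n)
}

#' Median and quartiles of a coefficient set
#'
#' Linear-interpolation quantiles (the standard convention) summarizing
#' per-participant Spearman coefficients at the group level.
#'
#' @param values numeric vector (at least 3 values).
#' @return Named vector `c(median, q1, q3)`.
#' @export
groupSummary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Welch t statistic from group summaries
#'
#' Two-sample t statistic with unpooled variances, computed directly from
#' printed group means, standard deviations and sizes:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return The t statistic (antisymmetric under swapping groups).
#' @export
welchTFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  if (se == 0) stop("zero variance in both groups")
  (mean1 - mean2) / se
}

#' Full device-agreement comparison
#'
#' Per-feature Wilcoxon agreement tests (both modes available), the
#' sign-concordance percentage and group quartile summaries for two devices'
#' per-participant trend coefficient matrices.
#'
#' @param coefA,coefB participants x features coefficient matrices (same
#'   participant order; shared column names).
#' @param mode Wilcoxon mode passed to [deviceAgreementTest()].
#' @return A [DeviceComparison-class].
#' @export
compareDevices <- function(coefA, coefB, mode = c("signed_rank", "rank_sum")) {
  mode <- match.arg(mode)
  A <- .coef_matrix(coefA); B <- .coef_matrix(coefB)
  if (!identical(rownames(A), rownames(B)))
    stop("participant sets differ between devices")
  feats <- colnames(A)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(A)))
  tests <- do.call(rbind, lapply(seq_along(feats), function(j) {
    tst <- deviceAgreementTest(A[, j], B[, j], mode)
    data.frame(feature = feats[j], W = tst$W, p_value = tst$p_value,
               mode = tst$mode)
  }))
  summ <- function(M) do.call(rbind, lapply(seq_along(feats), function(j) {
    s <- groupSummary(M[, j])
    data.frame(feature = feats[j], median = s[["median"]],
               q1 = s[["q1"]], q3 = s[["q3"]])
  }))
  new("DeviceComparison", coefA = A, coefB = B, tests = tests,
      similarFraction = signAgreement(A, B),
      summaryA = summ(A), summaryB = summ(B))
}
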