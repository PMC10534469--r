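mk_trend <- function(feature, rho, p, n = 90L)
  new("TrendResult", feature = feature, rho = rho, pValue = p,
      nWindows = as.integer(n))

test_that("Spearman trend handles monotone series, ties and transforms", {
  up <- spearmanTrend((1:20)^2, "rms")
  expect_equal(trendRho(up), 1)
  expect_lt(trendPValue(up), 1e-6)
  expect_equal(trendRho(spearmanTrend(exp(-(1:20)), "mdf")), -1)

  set.seed(7)
  for (i in 1:25) {
    y <- sample(1:6, 30, replace = TRUE)   # heavy ties
    got <- trendRho(spearmanTrend(y, "mnf"))
    expect_equal(got, brute_spearman(seq_along(y), y), tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms of the feature
  y <- rnorm(40)
  expect_equal(trendRho(spearmanTrend(y, "rms")),
               trendRho(spearmanTrend(exp(y), "rms")), tolerance = 1e-12)

  const <- spearmanTrend(rep(5, 30), "rms")
  expect_true(is.na(trendRho(const)))
  expect_error(spearmanTrend(c(1, 2, 3, 4), "rms"), "at least 5")
})

test_that("fatigue rule requires all three trends in the right direction", {
  call <- classifyFatigue(list(rms = mk_trend("rms", 0.9, 1e-7),
                               mdf = mk_trend("mdf", -0.9, 1e-7),
                               mnf = mk_trend("mnf", -0.9, 1e-7)))
  expect_true(isFatigued(call))

  inverted <- classifyFatigue(list(rms = mk_trend("rms", -0.9, 1e-7),
                                   mdf = mk_trend("mdf", 0.9, 1e-7),
                                   mnf = mk_trend("mnf", 0.9, 1e-7)))
  expect_false(isFatigued(inverted))

  weak_mdf <- classifyFatigue(list(rms = mk_trend("rms", 0.9, 1e-7),
                                   mdf = mk_trend("mdf", -0.1, 0.4),
                                   mnf = mk_trend("mnf", -0.9, 1e-7)))
  expect_false(isFatigued(weak_mdf))

  undef <- classifyFatigue(list(rms = mk_trend("rms", NA_real_, NA_real_),
                                mdf = mk_trend("mdf", -0.9, 1e-7),
                                mnf = mk_trend("mnf", -0.9, 1e-7)))
  expect_true(is.na(isFatigued(undef)))
})

test_that("strengthening trends never turns a fatigued call off", {
  # anchor: a clearly fatigued profile stays fatigued when strengthened
  strong <- list(rms = mk_trend("rms", 0.6, 0.01),
                 mdf = mk_trend("mdf", -0.6, 0.01),
                 mnf = mk_trend("mnf", -0.6, 0.01))
  expect_true(isFatigued(classifyFatigue(strong)))

  set.seed(15)
  hits <- 0L
  for (i in 1:100) {
    rho <- c(runif(1, 0.2, 1), runif(2, -1, -0.2))
    p <- runif(3, 0, 0.08)
    base <- classifyFatigue(list(rms = mk_trend("rms", rho[1], p[1]),
                                 mdf = mk_trend("mdf", rho[2], p[2]),
                                 mnf = mk_trend("mnf", rho[3], p[3])))
    gain <- runif(1, 1, 1 / max(abs(rho)))
    stronger <- classifyFatigue(list(
      rms = mk_trend("rms", rho[1] * gain, p[1] / 2),
      mdf = mk_trend("mdf", rho[2] * gain, p[2] / 2),
      mnf = mk_trend("mnf", rho[3] * gain, p[3] / 2)))
    if (isTRUE(isFatigued(base))) {
      hits <- hits + 1L
      expect_true(isFatigued(stronger))
    }
  }
  expect_gt(hits, 0L)   # the property was actually exercised
})

test_that("sign agreement counts fully concordant participants", {
  mkA <- function(n) matrix(c(runif(n, 0.2, 1), runif(2 * n, -1, -0.2)),
                            ncol = 3, dimnames = list(paste0("P", 1:n),
                                                      c("rms", "mdf", "mnf")))
  set.seed(2)
  A <- mkA(34)
  B <- A + matrix(rnorm(102, 0, 0.05), ncol = 3)   # same signs
  flip <- 27:34                                     # 8 discordant
  B[flip, 1] <- -B[flip, 1]
  expect_equal(signAgreement(A, B), 100 * 26 / 34, tolerance = 1e-9)
  expect_equal(signAgreement(A, A), 100)
  half <- A; half[1:17, 2] <- -half[1:17, 2]
  expect_equal(signAgreement(A, half), 50)
  expect_error(signAgreement(A, B[1:33, ]), "participants")
  B2 <- B; rownames(B2)[1] <- "other"
  expect_error(signAgreement(A, B2), "differ")
})

test_that("agreement test matches exact enumeration and behaves sanely", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(6:8, 1)
    a <- runif(n); b <- runif(n)
    got <- deviceAgreementTest(a, b, mode = "signed_rank")
    ref <- enum_signed_rank(a, b)
    expect_equal(got$W, ref$V)
    expect_equal(got$p_value, ref$p, tolerance = 1e-12)
  }

  a <- runif(10)
  same <- deviceAgreementTest(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$W, 0)

  shifted <- deviceAgreementTest(a, a + 5, mode = "signed_rank")
  expect_lt(shifted$p_value, 0.01)
  shifted2 <- deviceAgreementTest(a, a + 5, mode = "rank_sum")
  expect_lt(shifted2$p_value, 0.01)
  expect_error(deviceAgreementTest(a[1:3], a[1:3]), "at least 5")
  expect_error(deviceAgreementTest(a, a[1:5]), "paired")
})

test_that("group summary uses linear-interpolation quartiles", {
  s <- groupSummary(c(0.46, 0.73, 0.91))
  expect_equal(s[["median"]], 0.73)
  eq <- groupSummary(rep(0.5, 7))
  expect_equal(unname(eq), rep(0.5, 3))
  set.seed(30)
  for (i in 1:25) {
    v <- rnorm(sample(3:40, 1))
    s <- groupSummary(v)
    expect_equal(s[["q1"]], brute_quantile7(v, 0.25), tolerance = 1e-12)
    expect_equal(s[["median"]], brute_quantile7(v, 0.5), tolerance = 1e-12)
    expect_equal(s[["q3"]], brute_quantile7(v, 0.75), tolerance = 1e-12)
  }
})

test_that("summary t statistic is Welch's and antisymmetric", {
  expect_equal(welchTFromSummary(23.9, 3.9, 20, 24.2, 3.8, 14), -0.224,
               tolerance = 0.005)
  expect_equal(welchTFromSummary(1.5, 1.7, 20, 1.7, 1.9, 14), -0.315,
               tolerance = 0.005)
  expect_equal(welchTFromSummary(5, 1, 10, 5, 1, 10), 0)
  expect_equal(welchTFromSummary(3, 1.1, 9, 2, 0.8, 12),
               -welchTFromSummary(2, 0.8, 12, 3, 1.1, 9))
  expect_error(welchTFromSummary(1, 0, 5, 1, 0, 5), "zero variance")
})

test_that("comparing a device with itself reports full agreement", {
  set.seed(44)
  A <- matrix(runif(30, -1, 1), ncol = 3,
              dimnames = list(paste0("P", 1:10), c("rms", "mdf", "mnf")))
  cmp <- compareDevices(A, A)
  expect_equal(similarFraction(cmp), 100)
  expect_true(all(agreementTests(cmp)$p_value == 1))
  jittered <- A + matrix(rnorm(30, 0, 1e-3), ncol = 3)
  cmp2 <- compareDevices(A, jittered)
  expect_true(all(agreementTests(cmp2)$p_value > 0.05))
})
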