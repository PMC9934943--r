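pm <- function(a, b, ...) pairedMeasurements(seq_along(a), a, b, ...)

test_that("Bland-Altman bias, CI and limits of agreement are exact", {
  x <- c(3.2, 5.1, 4.4, 6.0)
  ba0 <- blandAltman(pm(x, x))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loaLower, ba0$loaUpper), c(0, 0))
  ba2 <- blandAltman(pm(x + 2, x))
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd, 0)
  expect_equal(ba2$biasCi95, c(2, 2))
  # d = (-1, 0, 1, 0): sample SD sqrt(2/3), LoA -/+ 1.96 * that
  ba <- blandAltman(pm(c(-1, 0, 1, 0), c(0, 0, 0, 0)))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ba$sd, 0.8165, tolerance = 1e-4)
  expect_equal(ba$loaUpper, 1.96 * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ba$biasCi95,
               c(-1, 1) * qt(0.975, 3) * sqrt(2 / 3) / 2, tolerance = 1e-12)
  expect_error(pairedMeasurements("p1", 1, 2), "two patients")
})

test_that("duplicate-difference SD estimator matches its algebra", {
  expect_equal(withinPairSd(pm(c(1, 2, 3), c(1, 2, 3))), 0)
  # every |d| = c gives c / sqrt(2)
  expect_equal(withinPairSd(pm(c(1, 2, 3, 4), c(0.5, 2.5, 2.5, 4.5))),
               0.5 / sqrt(2), tolerance = 1e-12)
  expect_equal(withinPairSd(pm(c(2, -2, 2, -2), c(0, 0, 0, 0))), sqrt(2),
               tolerance = 1e-12)
})

test_that("RC and RDC equal S times sqrt(2) times 1.96", {
  expect_equal(repeatabilityCoefficient(0), 0)
  expect_equal(repeatabilityCoefficient(1), 2.7719, tolerance = 1e-4)
  expect_equal(reproducibilityCoefficient(2.06), 5.7, tolerance = 0.02)
  expect_error(repeatabilityCoefficient(-1), "non-negative")
  set.seed(1)
  p <- pm(rnorm(10), rnorm(10))
  expect_equal(rcStatistic(p), withinPairSd(p) * sqrt(2) * 1.96)
})

test_that("sample-size planning reproduces the closed form and monotonicity", {
  expect_identical(planSampleSize(0.40, 0.05, 2), 12L)
  expect_identical(planSampleSize(0.20, 0.05, 2), 48L)
  expect_identical(planSampleSize(0.40, 0.05, 3), 6L)
  expect_error(planSampleSize(1.2), "between 0 and 1")
  expect_error(planSampleSize(0.4, 0.05, 1), ">= 2")
  prec <- seq(0.1, 0.9, by = 0.1)
  ns <- vapply(prec, planSampleSize, integer(1))
  expect_true(all(diff(ns) <= 0))
  ms <- vapply(2:6, function(m) planSampleSize(0.3, 0.05, m), integer(1))
  expect_true(all(diff(ms) <= 0))
})

test_that("BCa bootstrap is deterministic, degenerate-safe and matches boot", {
  set.seed(5)
  p <- pm(rnorm(13), rnorm(13))
  ci1 <- bcaCi(rcStatistic, p, nBoot = 500, seed = 9)
  ci2 <- bcaCi(rcStatistic, p, nBoot = 500, seed = 9)
  expect_identical(ci1, ci2)
  ci3 <- bcaCi(rcStatistic, p, nBoot = 500, seed = 10)
  expect_false(identical(ci1$lower, ci3$lower))
  # constant statistic collapses to a point interval
  cst <- bcaCi(function(x) 7, p, nBoot = 100, seed = 1)
  expect_equal(c(cst$lower, cst$upper), c(7, 7))
  # independent reference implementation (boot::boot.ci, BCa)
  d <- p@valuesA - p@valuesB
  bo <- boot::boot(d, function(x, i) sqrt(sum(x[i]^2) / (2 * length(i))) *
                     sqrt(2) * 1.96, R = 4000)
  ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  mine <- bcaCi(rcStatistic, p, nBoot = 4000, seed = 77)
  expect_equal(c(mine$lower, mine$upper), ref, tolerance = 0.05)
})

test_that("RC and RDC scale linearly with injected noise", {
  set.seed(21)
  truth <- runif(200, 2, 10)
  slopes <- vapply(c(0.5, 1, 2), function(sig) {
    p <- pm(truth + rnorm(200, 0, sig), truth + rnorm(200, 0, sig))
    rcStatistic(p) / sig
  }, numeric(1))
  expect_true(all(abs(slopes - 2.772) / 2.772 < 0.05))
})

test_that("bias estimator is unbiased under a constant shift", {
  set.seed(31)
  delta <- 1.5
  biases <- replicate(500, {
    tr <- rnorm(13, 5, 2)
    mean((tr + delta + rnorm(13, 0, 0.6)) - (tr + rnorm(13, 0, 0.6)))
  })
  se <- sd(biases) / sqrt(length(biases))
  expect_lt(abs(mean(biases) - delta), 3 * se)
})

test_that("precision report builds the comparison table and flags config errors", {
  set.seed(8)
  ids <- sprintf("P%02d", 1:10)
  truth <- runif(10, 2, 10)
  long <- do.call(rbind, lapply(c("OBS1_RUN1", "OBS1_RUN2", "OBS2", "ML"),
    function(o) data.frame(patient_id = ids, observer = o,
                           parameter = "recruitment", value = truth)))
  rep0 <- precisionReport(long, nBoot = 50, seed = 1)
  expect_equal(nrow(rep0), 3)
  expect_true(all(rep0$bias == 0))
  expect_true(all(rep0$coefficient == 0))
  expect_equal(rep0$coefficient_type[rep0$comparison == "intra_observer"], "RC")
  expect_setequal(rep0$comparison, comparisonTypes)
  noMl <- long[long$observer != "ML", ]
  expect_error(precisionReport(noMl, comparisons = "inter_human_ml",
                               nBoot = 50),
               "configuration error")
  expect_silent(precisionReport(noMl, comparisons = "intra_observer",
                                nBoot = 50, seed = 2))
})
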