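test_that("noiseless logistic series are recovered exactly", {
  t <- seq(0, 48, by = 2)
  fit <- fitLogistic(CultureSeries("c1", t, logisticCurve(t, 100, 0.4, 24)))
  expect_true(grew(fit))
  expect_equal(capacity(fit), 100, tolerance = 1e-8)
  expect_equal(rate(fit), 0.4, tolerance = 1e-8)
  expect_equal(halfTime(fit), 24, tolerance = 1e-8)
  expect_equal(rSquared(fit), 1, tolerance = 1e-9)

  # property: exact recovery across random parameter draws
  set.seed(42)
  for (i in 1:100) {
    K <- runif(1, 50, 150); r <- runif(1, 0.1, 1); L <- runif(1, 10, 40)
    b <- runif(1, 0, 20)
    f <- fitLogistic(CultureSeries("p", t, logisticCurve(t, K, r, L, b)))
    expect_true(abs(capacity(f) - K) < 1e-6)
    expect_true(abs(rate(f) - r) < 1e-6)
    expect_true(abs(halfTime(f) - L) < 1e-6)
  }
})

test_that("noisy series recover parameters within 5%, agreeing with a grid-search oracle", {
  t <- seq(0, 48, by = 2)
  set.seed(8)
  y <- logisticCurve(t, 100, 0.4, 24) + rnorm(length(t), 0, 2)
  fit <- fitLogistic(CultureSeries("noisy", t, y), fitConfig(fitBaseline = FALSE))
  oracle <- gridSearchLogistic(t, y)
  expect_lt(abs(capacity(fit) - 100) / 100, 0.05)
  expect_lt(abs(rate(fit) - 0.4) / 0.4, 0.05)
  expect_lt(abs(halfTime(fit) - 24) / 24, 0.05)
  # the exhaustive search lands on the same optimum (to grid resolution)
  expect_lt(abs(capacity(fit) - oracle$K), 1)
  expect_lt(abs(rate(fit) - oracle$r), 0.01)
  expect_lt(abs(halfTime(fit) - oracle$L), 0.25)
})

test_that("flat series are flagged as no growth with NA parameters", {
  t <- seq(0, 48, by = 2)
  fit <- fitLogistic(CultureSeries("flat", t, rep(10, length(t))))
  expect_false(grew(fit))
  expect_true(is.na(capacity(fit)))
  expect_true(is.na(halfTime(fit)))
  expect_true(is.na(aucValue(fit)))
  expect_false(detectNoGrowth(CultureSeries("flat", t, rep(10, length(t)))))
})

test_that("series shorter than 4 points are rejected", {
  expect_error(CultureSeries("x", c(0, 1, 2), c(1, 2, 3)), "4 time points")
  expect_error(CultureSeries("x", c(0, 2, 1, 3), 1:4), "increasing")
})

test_that("no-growth capacity threshold is exclusive below", {
  t <- seq(0, 48, by = 2)
  ts <- CultureSeries("b", t, logisticCurve(t, 8, 0.4, 24))
  kFit <- capacity(fitLogistic(ts, fitConfig(kMin = 1)))
  # K exactly at the threshold still counts as growth
  expect_true(detectNoGrowth(ts, fitConfig(kMin = kFit)))
  expect_false(detectNoGrowth(ts, fitConfig(kMin = kFit + 1e-6)))
})

test_that("AUC matches independent quadrature and is linear in K", {
  t <- seq(0, 48, by = 2)
  fit <- fitLogistic(CultureSeries("a", t, logisticCurve(t, 100, 0.4, 24)))
  a <- aucLogistic(fit, 0, 48)
  expect_equal(a, trapezoidAUC(100, 0.4, 24, 0, 48),
               tolerance = 1e-6)
  expect_equal(a, 2400, tolerance = 1e-4)
  fit2 <- fitLogistic(CultureSeries("a2", t, logisticCurve(t, 200, 0.4, 24)))
  expect_equal(aucLogistic(fit2, 0, 48), 2 * a, tolerance = 1e-6)
  # degenerate capacity
  zero <- new("GrowthFit", cultureId = "z", K = 0, r = 0.4, L = 24,
              baseline = 0, auc = 0, rSquared = 1,
              ciLower = c(K = 0, r = 0, L = 0),
              ciUpper = c(K = 0, r = 0, L = 0),
              grew = TRUE, converged = TRUE)
  expect_identical(aucLogistic(zero, 0, 48), 0)
  # no-growth fit yields NA
  flat <- fitLogistic(CultureSeries("f", t, rep(1, length(t))))
  expect_true(is.na(aucLogistic(flat, 0, 48)))
})

test_that("AUC agrees with the closed form across random fits", {
  t <- seq(0, 48, by = 2)
  set.seed(11)
  for (i in 1:20) {
    K <- runif(1, 50, 150); r <- runif(1, 0.1, 1); L <- runif(1, 10, 40)
    f <- fitLogistic(CultureSeries("p", t, logisticCurve(t, K, r, L)))
    closed <- (K / r) * log((1 + exp(r * (48 - L))) / (1 + exp(r * (0 - L))))
    expect_equal(aucLogistic(f, 0, 48), closed, tolerance = 1e-6)
  }
})

test_that("fits are invariant to adding a constant when the baseline is fitted", {
  t <- seq(0, 48, by = 2)
  y <- logisticCurve(t, 100, 0.4, 24, 5)
  f1 <- fitLogistic(CultureSeries("s1", t, y))
  f2 <- fitLogistic(CultureSeries("s2", t, y + 37))
  expect_equal(capacity(f1), capacity(f2), tolerance = 1e-6)
  expect_equal(rate(f1), rate(f2), tolerance = 1e-6)
  expect_equal(halfTime(f1), halfTime(f2), tolerance = 1e-6)
  expect_equal(baseline(f2) - baseline(f1), 37, tolerance = 1e-6)
})

test_that("confidence bounds bracket the estimate and shrink with less noise", {
  t <- seq(0, 48, by = 2)
  set.seed(3)
  fitAt <- function(sd) {
    y <- logisticCurve(t, 100, 0.4, 24) + rnorm(length(t), 0, sd)
    fitLogistic(CultureSeries("ci", t, y), fitConfig(fitBaseline = FALSE))
  }
  f <- fitAt(2)
  ci <- confint95(f)
  expect_true(all(ci["lower", ] <= c(capacity(f), rate(f), halfTime(f))))
  expect_true(all(ci["upper", ] >= c(capacity(f), rate(f), halfTime(f))))
  fTight <- fitAt(0.2)
  expect_lt(diff(confint95(fTight)[, "L"]), diff(ci[, "L"]))
})

test_that("standardizing by the untreated group centers it at 0 with unit spread", {
  v <- c(10, 12, 14, 16, 18)
  d <- c(0, 0, 0, 0.1, 0.1)
  z <- standardizeByUntreated(v, d)
  expect_equal(mean(z[d == 0]), 0, tolerance = 1e-12)
  expect_equal(sd(z[d == 0]), 1, tolerance = 1e-12)
  # hand computation: untreated mean 12, sd 2, so 16 -> 2
  expect_equal(z[4], 2)
  # all groups identical to untreated -> every group centered at 0
  d2 <- rep(c(0, 0.1, 0.2), each = 3)
  z2 <- standardizeByUntreated(rep(c(10, 12, 14), 3), d2)
  expect_equal(unname(as.numeric(tapply(z2, d2, mean))), c(0, 0, 0),
               tolerance = 1e-12)
  # property: untreated group always standardizes to mean 0, sd 1
  set.seed(5)
  for (i in 1:25) {
    vv <- rnorm(30, 20, 4)
    dd <- sample(c(0, 0.05, 0.25), 30, replace = TRUE)
    if (sum(dd == 0) < 2) next
    zz <- standardizeByUntreated(vv, dd)
    expect_equal(mean(zz[dd == 0]), 0, tolerance = 1e-12)
    expect_equal(sd(zz[dd == 0]), 1, tolerance = 1e-12)
  }
  expect_error(standardizeByUntreated(c(5, 5, 7), c(0, 0, 0.1)),
               "zero standard deviation")
  expect_error(standardizeByUntreated(c(5, 7), c(0, 0.1)), "at least 2")
})
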