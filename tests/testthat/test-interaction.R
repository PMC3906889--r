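stdDoses <- c(0, 0.05, 0.1, 0.15, 0.2, 0.25)

test_that("reference model summarizes replicates per dose with censoring excluded", {
  # constant replicates collapse band and center onto the value
  rm0 <- buildReference(data.frame(dose = rep(c(0, 0.1), each = 4),
                                   L = rep(30, 8)))
  expect_equal(centralL(rm0), c(30, 30))
  expect_equal(unname(referenceBand(rm0)["low", ]), c(30, 30))
  expect_equal(unname(referenceBand(rm0)["high", ]), c(30, 30))

  # 768 normal draws: center and band match independently computed quantiles
  set.seed(21)
  L <- rnorm(768, 30, 2)
  rm1 <- buildReference(data.frame(dose = rep(0, 768), L = L))
  expect_lt(abs(centralL(rm1) - 30), 0.3)
  expect_equal(unname(referenceBand(rm1)["low", ]),
               unname(quantile(L, 0.025)), tolerance = 1e-12)
  expect_equal(unname(referenceBand(rm1)["high", ]),
               unname(quantile(L, 0.975)), tolerance = 1e-12)
  expect_lt(abs(referenceBand(rm1)["low", ] - qnorm(0.025, 30, 2)), 0.3)
  expect_lt(abs(referenceBand(rm1)["high", ] - qnorm(0.975, 30, 2)), 0.3)

  # censored replicates are dropped; the center is over the grown half
  rm2 <- buildReference(data.frame(dose = rep(0, 10),
                                   L = c(rep(30, 5), rep(NA, 5))))
  expect_equal(centralL(rm2), 30)
  expect_equal(nReplicates(rm2), 5L)
  expect_error(
    buildReference(data.frame(dose = c(0, 0, 0.1), L = c(30, 31, 32))),
    "dose 0.1")
  # mean central tendency available by configuration
  rmMean <- buildReference(data.frame(dose = rep(0, 3), L = c(10, 20, 60)),
                           center = "mean")
  expect_equal(centralL(rmMean), 30)
})

test_that("planted quadratic responses are scored exactly", {
  ref <- flatReference()
  # reference scored against itself is null
  self <- scoreInteraction(plantedDoseResponse("self", ref, 0, 0, 0), ref)
  expect_equal(orfEffect(self), 0, tolerance = 1e-9)
  expect_equal(interactionValue(self), 0, tolerance = 1e-9)

  dr <- plantedDoseResponse("p", ref, K0 = 5, B = 40, C = -80)
  res <- scoreInteraction(dr, ref)
  expect_equal(orfEffect(res), 5, tolerance = 1e-9)
  expect_equal(interactionValue(res), 40 * 0.25 - 80 * 0.25^2,
               tolerance = 1e-6)
  expect_equal(interactionValue(res), 5, tolerance = 1e-6)
  expect_equal(tier(res), 0L)
  # recovered coefficients match the planted polynomial
  expect_equal(unname(quadCoef(res)), c(0, 40, -80), tolerance = 1e-9)
  # adjusted response at dose 0 is exactly zero
  expect_identical(adjustedResponse(res)$L[1], 0)

  # censoring the top doses re-evaluates the quadratic at the highest
  # dose with measurable growth
  dr2 <- plantedDoseResponse("p2", ref, 5, 40, -80, censorIdx = 5:6)
  res2 <- scoreInteraction(dr2, ref)
  expect_equal(tier(res2), 2L)
  expect_equal(dMaxScored(res2), 0.15)
  expect_equal(interactionValue(res2), 40 * 0.15 - 80 * 0.15^2,
               tolerance = 1e-6)
  expect_equal(interactionValue(res2), 4.2, tolerance = 1e-6)

  # fewer than 3 grown doses: INT is NA but the tier still ranks
  dr3 <- plantedDoseResponse("p3", ref, 5, 40, -80, censorIdx = 3:6)
  res3 <- scoreInteraction(dr3, ref)
  expect_true(is.na(interactionValue(res3)))
  expect_equal(tier(res3), 4L)
  # no growth at dose 0 is undefined
  expect_error(
    scoreInteraction(DoseResponse("z", stdDoses,
                                  c(NA, 31, 32, 33, 34, 35)), ref),
    "dose 0")
})

test_that("the zero-dose identity and shift/monotonicity properties hold", {
  set.seed(31)
  ref <- buildReference(data.frame(
    dose = rep(stdDoses, each = 20),
    L = as.vector(sapply(refShapeOracle(list(refL0 = 30, refSlope = 30,
                                             refQuad = 80), stdDoses),
                         function(mu) rnorm(20, mu, 1)))))
  for (i in 1:25) {
    Y <- centralL(ref) + rnorm(6, 0, 3)
    dr <- DoseResponse(sprintf("s%d", i), stdDoses, Y)
    res <- scoreInteraction(dr, ref)
    expect_identical(adjustedResponse(res)$L[1], 0)
    # a constant shift of the whole response is absorbed into K0
    drShift <- DoseResponse("shift", stdDoses, Y + 7)
    resShift <- scoreInteraction(drShift, ref)
    expect_equal(orfEffect(resShift), orfEffect(res) + 7, tolerance = 1e-9)
    expect_equal(interactionValue(resShift), interactionValue(res),
                 tolerance = 1e-9)
    # adding a non-negative dose-increasing term strictly increases INT
    delta <- runif(1, 0.5, 5); gam <- runif(1, 0, 20)
    drUp <- DoseResponse("up", stdDoses, Y + delta * stdDoses + gam * stdDoses^2)
    expect_gt(interactionValue(scoreInteraction(drUp, ref)),
              interactionValue(res))
  }
})

test_that("classification uses strict thresholds and tiers", {
  ref <- flatReference()
  mk <- function(int) {
    # realize a response whose quadratic evaluates to the requested INT
    B <- int / 0.25
    classifyInteraction(
      scoreInteraction(plantedDoseResponse("m", ref, 0, B, 0), ref),
      Thresholds(10, -16))
  }
  mkExact <- function(int, tierN = 0L) classifyInteraction(
    new("InteractionResult", strainId = "x", K0 = 0,
        coef = c(A = 0, B = int / 0.25, C = 0), INT = int,
        dMaxScored = 0.25, tier = tierN, quadR2 = 1,
        intClass = NA_character_, qcFlags = character(),
        adjustedL = 0, adjustedDoses = 0),
    Thresholds(10, -16))
  expect_equal(interactionClass(mk(10.5)), "deletion_enhancer")
  expect_equal(interactionClass(mkExact(10)), "none")   # strict inequality
  expect_equal(interactionClass(mkExact(-16)), "none")  # strict inequality
  expect_equal(interactionClass(mk(-16.5)), "deletion_suppressor")
  # wild-type screen cuts
  mkWT <- function(int) classifyInteraction(
    scoreInteraction(plantedDoseResponse("m", ref, 0, int / 0.25, 0), ref),
    Thresholds(10, -12))
  expect_equal(interactionClass(mkWT(-12.5)), "deletion_suppressor")
  # tiered no-growth strain with unfit quadratic is an enhancer
  tiered <- classifyInteraction(
    scoreInteraction(plantedDoseResponse("t", ref, 0, 40, 0,
                                         censorIdx = 3:6), ref),
    Thresholds(10, -16))
  expect_equal(interactionClass(tiered), "deletion_enhancer")
  expect_error(Thresholds(-1, -5))
})

test_that("ranking groups by tier then interaction value, matching a comparison sort", {
  tbl <- data.frame(
    strain = sprintf("s%02d", 1:10),
    tier = c(2L, 0L, 0L, 1L, 0L, 2L, 0L, 3L, 1L, 0L),
    INT = c(3, 50, 10, NA, 20, -1, 10, 2, 8, -30)
  )
  ranked <- rankInteractions(tbl)
  expect_identical(ranked$strain, bruteRank(tbl)$strain)
  # tiered strains precede even very large scored enhancers
  expect_lt(which(ranked$strain == "s01"), which(ranked$strain == "s02"))
  # within a tier, larger INT first; ties broken by id
  expect_lt(which(ranked$strain == "s05"), which(ranked$strain == "s03"))
  expect_lt(which(ranked$strain == "s03"), which(ranked$strain == "s07"))
})

test_that("gene-drug scores difference out dose and deletion effects", {
  expect_equal(geneDrugScore(30, 30, 30, 30), 0)
  # +3 h on control, +8 h on drug -> 5 h interaction
  expect_equal(geneDrugScore(38, 33, 30, 30), 5)
  # antisymmetry under swapping deletion and reference
  expect_equal(geneDrugScore(38, 33, 30, 30),
               -geneDrugScore(30, 30, 38, 33))
  expect_true(is.na(geneDrugScore(NA, 33, 30, 30)))
})

test_that("overlapping-ORF pairs with shared effects correlate strongly", {
  set.seed(41)
  shared <- rnorm(50, 0, 15)
  a <- shared + rnorm(50, 0, 1)
  b <- shared + rnorm(50, 0, 1)
  oc <- overlapOrfCorrelation(a, b)
  expect_gt(oc$correlation, 0.8)
  expect_equal(oc$correlation, cor(a, b), tolerance = 1e-12)
  expect_equal(nrow(oc$table), 50)
  # perfectly concordant pairs
  expect_equal(overlapOrfCorrelation(shared, shared)$correlation, 1)
  # independent pairs decorrelate
  expect_lt(abs(overlapOrfCorrelation(rnorm(100), rnorm(100))$correlation),
            0.3)
  expect_error(overlapOrfCorrelation(c(1, NA, 3), c(1, 2, NA)), "at least 3")
})

test_that("quality flags automate the low-confidence exclusion criteria", {
  ref <- flatReference()
  clean <- classifyInteraction(
    scoreInteraction(plantedDoseResponse("c", ref, 0, 60, 40), ref))
  expect_identical(flags(qcFlags(clean)), character(0))

  bigK0 <- scoreInteraction(plantedDoseResponse("k", ref, 25, 60, 40), ref)
  expect_true("large_zero_dose_effect" %in% flags(qcFlags(bigK0)))

  # response flattening at the top dose while the call is large
  plateau <- scoreInteraction(
    plantedDoseResponse("pl", ref, 0, 120, -240), ref)
  expect_equal(interactionValue(plateau), 15, tolerance = 1e-6)
  expect_true("plateau_response" %in% flags(qcFlags(plateau)))

  weak <- scoreInteraction(plantedDoseResponse("w", ref, 0, 8, 0), ref)
  expect_true("weak_effect" %in% flags(qcFlags(weak)))

  # interaction already present with the wild-type allele
  companion <- scoreInteraction(plantedDoseResponse("c", ref, 0, 80, 0), ref)
  flagged <- qcFlags(clean, companion = companion)
  expect_true("wildtype_context_interaction" %in% flags(flagged))

  # poorly quadratic dose response
  wiggly <- scoreInteraction(
    DoseResponse("wig", stdDoses,
                 centralL(ref) + c(0, 18, -14, 19, -12, 16)), ref)
  expect_lt(wiggly@quadR2, 0.8)
  expect_true("poor_quadratic_fit" %in% flags(qcFlags(wiggly)))

  # high confidence = classified and unflagged
  tb <- interactionTable(list(qcFlags(clean), qcFlags(bigK0)))
  expect_identical(tb$high_confidence, c(TRUE, FALSE))
})
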