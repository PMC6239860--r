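test_that("tabulation classifies free, binary and ternary particles", {
  tabs <- tabulateBinding(handBuiltRecords())
  tb <- tabs[["HDL.control"]]
  expect_s4_class(tb, "BindingTable")
  expect_equal(nTotal(tb), 6L)
  expect_equal(nFree(tb), 2L)
  expect_equal(nBinary(tb), 3L)
  expect_equal(nTernary(tb), 1L)
  expect_identical(multiplicityHistogram(tb), c("1" = 3L, "2" = 1L))
  expect_equal(boundFraction(tb), 4 / 6)

  # all-free table
  rec <- handBuiltRecords()
  rec$observed_protrusions <- 0L
  rec$ternary_partner <- NA_character_
  tb0 <- tabulateBinding(rec)[["HDL.control"]]
  expect_equal(nFree(tb0), 6L)
  expect_equal(boundFraction(tb0), 0)

  # conservation on a simulated population
  pop <- generatePopulation(smallConfig(n = 100, seed = 21))
  for (tb in tabulateBinding(pop))
    expect_equal(nFree(tb) + nBinary(tb) + nTernary(tb), nTotal(tb))
})

test_that("detection probability averages over the multiplicity model", {
  expect_equal(detectionProbability(0.9), 0.9)
  mult <- c("1" = 0.5, "2" = 0.5)
  expect_equal(detectionProbability(0.9, mult),
               0.5 * 0.9 + 0.5 * (1 - 0.1^2))
  # k = 1 reduces to the single-protrusion probability
  expect_equal(detectionProbability(0.77, c("1" = 1)), 0.77)
  expect_error(detectionProbability(0), "\\(0, 1\\]")
})

test_that("visibility-corrected fraction scales by 1/P and caps at 1", {
  mk <- function(nBound, nTot) new("BindingTable", className = "HDL",
    condition = "x", nTotal = as.integer(nTot),
    nFree = as.integer(nTot - nBound), nBinary = as.integer(nBound),
    nTernary = 0L, multiplicity = setNames(as.integer(nBound), "1"))
  gFull <- RodSphereGeometry(1e-9, rodLength = 8)  # P ~ 1
  tb <- mk(10, 100)
  expect_equal(correctedBoundFraction(tb, gFull), boundFraction(tb),
               tolerance = 1e-9)
  g10 <- RodSphereGeometry(10, rodLength = 8)      # P = 12/13
  expect_equal(correctedBoundFraction(tb, g10), 0.1 * 13 / 12)
  expect_equal(round(correctedBoundFraction(tb, g10), 4), 0.1083)
  # cap rule
  g30 <- RodSphereGeometry(30, rodLength = 8)      # P ~ 0.758
  expect_warning(capped <- correctedBoundFraction(mk(99, 100), g30),
                 "capped")
  expect_equal(capped, 1)
  # corrected >= observed, always
  set.seed(31)
  for (i in 1:20) {
    tb <- mk(sample(1:80, 1), 100)
    g <- RodSphereGeometry(runif(1, 5, 40), rodLength = 8)
    expect_gte(suppressWarnings(correctedBoundFraction(tb, g)),
               boundFraction(tb))
  }
})

test_that("ternary fractions divide bridges by each class total", {
  mk <- function(cls, nTot, nTern) new("BindingTable", className = cls,
    condition = "control", nTotal = as.integer(nTot),
    nFree = as.integer(nTot - nTern), nBinary = 0L,
    nTernary = as.integer(nTern),
    multiplicity = if (nTern) setNames(as.integer(nTern), "1") else integer(0))
  fr <- ternaryFractions(mk("HDL", 100, 12), mk("LDL", 60, 12))
  expect_equal(unname(fr), c(0.12, 0.20))
  expect_equal(unname(ternaryFractions(mk("HDL", 50, 0), mk("LDL", 30, 0))),
               c(0, 0))
  expect_error(ternaryFractions(mk("HDL", 100, 12), mk("LDL", 60, 10)),
               "inconsistent")
})

test_that("chi-square comparison matches the hand closed form", {
  mk <- function(cond, bound, free) new("BindingTable", className = "HDL",
    condition = cond, nTotal = as.integer(bound + free),
    nFree = as.integer(free), nBinary = as.integer(bound), nTernary = 0L,
    multiplicity = if (bound) setNames(as.integer(bound), "1") else integer(0))
  # identical proportions: statistic 0, p = 1
  r <- compareConditions(mk("a", 50, 50), mk("b", 50, 50), yates = FALSE)
  expect_equal(chiSquareStatistic(r), 0)
  expect_equal(pValue(r), 1)
  expect_false(isSignificant(r))
  # uncorrected Pearson, hand formula N(ad-bc)^2/(r1 r2 c1 c2)
  r <- compareConditions(mk("a", 10, 90), mk("b", 50, 50), yates = FALSE)
  expect_equal(chiSquareStatistic(r), handChiSquare(10, 90, 50, 50))
  expect_equal(chiSquareStatistic(r), 38.0952381, tolerance = 1e-6)
  expect_lt(pValue(r), 1e-9)
  # Yates-corrected closed form |ad - bc| reduced by n/2
  r <- compareConditions(mk("a", 3, 7), mk("b", 8, 2), yates = TRUE)
  expect_equal(chiSquareStatistic(r),
               handChiSquare(3, 7, 8, 2, yates = TRUE))
  expect_equal(chiSquareStatistic(r), 3.2323232, tolerance = 1e-6)
  # symmetry in table order and Yates <= uncorrected
  set.seed(41)
  for (i in 1:20) {
    a <- mk("a", sample(5:95, 1), sample(5:95, 1))
    b <- mk("b", sample(5:95, 1), sample(5:95, 1))
    expect_equal(chiSquareStatistic(compareConditions(a, b)),
                 chiSquareStatistic(compareConditions(b, a)))
    expect_lte(chiSquareStatistic(compareConditions(a, b, yates = TRUE)),
               chiSquareStatistic(compareConditions(a, b, yates = FALSE)))
  }
  # degenerate tables are refused
  expect_error(compareConditions(mk("a", 0, 100), mk("b", 0, 50)),
               "degenerate")
})

test_that("p-value display floors at 2.2e-16 but storage is exact", {
  expect_equal(formatPValue(1e-20), "< 2.2e-16")
  expect_false(formatPValue(1e-10) == "< 2.2e-16")
  mk <- function(cond, bound, free) new("BindingTable", className = "HDL",
    condition = cond, nTotal = as.integer(bound + free),
    nFree = as.integer(free), nBinary = as.integer(bound), nTernary = 0L,
    multiplicity = setNames(as.integer(bound), "1"))
  r <- compareConditions(mk("a", 40, 360), mk("b", 202, 198))
  expect_lt(pValue(r), 2.2e-16)   # floor-level contrast
  expect_gt(pValue(r), 0)
})

test_that("corrected estimator recovers a configured propensity", {
  cfg <- twoArmConfig(0.099, 0.505, n = 5000, seed = 51)
  tabs <- tabulateBinding(generatePopulation(cfg))
  g <- RodSphereGeometry(12.28, rodLength = 8)
  mult <- cfg@multiplicity[["HDL"]]
  truths <- c(A = 0.099, B = 0.505)
  for (cond in names(truths)) {
    tb <- tabs[[paste("HDL", cond, sep = ".")]]
    est <- correctedBoundFraction(tb, g, mult)
    se <- sqrt(truths[[cond]] * (1 - truths[[cond]]) / 5000)
    expect_lt(abs(est - truths[[cond]]), 4 * se)
    expect_gte(est, boundFraction(tb))
  }
})
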