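test_that("config validation catches out-of-range parameters", {
  expect_s4_class(simulationConfig(), "SimulationConfig")
  expect_error(simulationConfig(nParticles = 0), "nParticles")
  expect_error(simulationConfig(
    propensities = data.frame(condition = "a", class = "HDL",
                              propensity = 1.2)), "propensity")
  expect_error(simulationConfig(
    multiplicity = list(HDL = c("1" = 0.5, "2" = 0.4))), "summing to 1")
  expect_error(simulationConfig(
    timecourse = list(control = list(times = c(0, 10, 5),
                                     decrease = c(0, 0.1, 0.2)))),
    "increasing")
})

test_that("generated populations conserve particles and obey the schema", {
  cfg <- smallConfig(n = 120, seed = 5)
  pop <- generatePopulation(cfg)
  expect_equal(nrow(pop), 120 * 3 * 4)  # classes x conditions
  expect_silent(validateParticles(pop))
  expect_true(all(pop$observed_protrusions <= pop$true_protrusions))
  expect_true(all(pop$diameter_long > 0 & pop$diameter_perp > 0))
  # determinism: identical config + seed give identical tables
  expect_identical(pop, generatePopulation(cfg))
  # and a different seed does not
  cfg2 <- smallConfig(n = 120, seed = 6)
  expect_false(identical(pop, generatePopulation(cfg2)))
})

test_that("zero propensity yields an all-free population", {
  cfg <- twoArmConfig(0, 0, n = 200, seed = 2)
  pop <- generatePopulation(cfg)
  expect_true(all(pop$observed_protrusions == 0))
  expect_true(all(pop$true_protrusions == 0))
})

test_that("geometric occlusion reproduces the analytic visibility", {
  # all particles bound with exactly one protrusion on a fixed 10 nm
  # sphere: the observed bound fraction estimates P(10, 8) = 12/13
  cfg <- simulationConfig(
    classes = data.frame(name = "HDL", diameter_mean = 10, diameter_sd = 0),
    propensities = data.frame(condition = "A", class = "HDL",
                              propensity = 1),
    multiplicity = list(HDL = c("1" = 1)),
    ternary = list(), timecourse = list(),
    noiseSd = 0, nParticles = 20000L, seed = 7)
  pop <- generatePopulation(cfg)
  frac <- mean(pop$observed_protrusions >= 1)
  p <- 12 / 13
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 20000))
  # pooled over truth: observed / true protrusions also estimates P
  expect_lt(abs(sum(pop$observed_protrusions) / sum(pop$true_protrusions) - p),
            3 * sqrt(p * (1 - p) / 20000))
})

test_that("monte carlo visibility has its degenerate limits", {
  expect_equal(simulateVisibleFraction(10, 0, 1e4, seed = 1), 0)
  expect_gt(simulateVisibleFraction(1e-6, 8, 1e4, seed = 1), 0.999)
  # reproducible under a fixed seed
  expect_identical(simulateVisibleFraction(10, 8, 1e4, seed = 3),
                   simulateVisibleFraction(10, 8, 1e4, seed = 3))
})

test_that("ternary bridging cross-references pairs and hits its targets", {
  cfg <- smallConfig(n = 5000, seed = 11)
  tern <- generateTernaryPopulation(cfg, conditions = "control")
  expect_silent(validateParticles(tern))
  hdl <- tern[tern$class == "HDL", ]
  ldl <- tern[tern$class == "LDL", ]
  # every bridged HDL names an LDL that names it back
  bh <- hdl[!is.na(hdl$ternary_partner), ]
  bl <- ldl[!is.na(ldl$ternary_partner), ]
  expect_equal(nrow(bh), nrow(bl))
  expect_setequal(bh$ternary_partner, bl$particle_id)
  expect_setequal(bl$ternary_partner, bh$particle_id)
  # bridged particles always show the bridge
  expect_true(all(bh$observed_protrusions >= 1))
  # configured control targets (0.122 per HDL, ~0.195 per LDL) are
  # recovered within 3 binomial SEs
  fH <- nrow(bh) / nrow(hdl)
  seH <- sqrt(0.122 * 0.878 / nrow(hdl))
  expect_lt(abs(fH - 0.122), 3 * seH)
  fL <- nrow(bl) / nrow(ldl)
  expect_lt(abs(fL - 0.122 / 0.626), 3 * seH * nrow(hdl) / nrow(ldl))
})

test_that("zero bridge probability produces no ternary records", {
  cfg <- smallConfig(n = 500, seed = 12)
  cfg@ternary$probability <- 0
  tern <- generateTernaryPopulation(cfg, conditions = "control")
  expect_true(all(is.na(tern$ternary_partner)))
})

test_that("forced bridging equates ternary and bound fractions", {
  cfg <- smallConfig(n = 2000, seed = 13)
  cfg@ternary$probability <- 1
  cfg@ternary$hdl_propensity["control"] <- 0.4
  tern <- generateTernaryPopulation(cfg, conditions = "control")
  hdl <- tern[tern$class == "HDL", ]
  tf <- mean(!is.na(hdl$ternary_partner))
  bf <- mean(hdl$observed_protrusions >= 1 | !is.na(hdl$ternary_partner))
  expect_equal(tf, bf)  # every bound HDL is bridged, bridges are visible...
  expect_lt(abs(tf - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
})

test_that("timecourse scales the diameter mean by the configured decrease", {
  cfg <- smallConfig(n = 5000, seed = 14)
  tc <- generateTimecourse(cfg, conditions = "control")
  m <- aggregate(true_diameter ~ time_min, tc, mean)
  expect_equal(m$time_min, c(0, 15, 40, 120, 480))
  # time 0 uses the unscaled mean
  se <- 1.91 / sqrt(5000)
  expect_lt(abs(m$true_diameter[m$time_min == 0] - 12.28), 4 * se)
  expect_lt(abs(m$true_diameter[m$time_min == 480] - 12.28 * 0.70), 4 * se)
  # interpolation between configured points, clamped beyond the range
  expect_equal(timecourseDecrease(cfg, "control", 80),
               0.17 + (0.21 - 0.17) * (80 - 40) / (120 - 40))
  expect_equal(timecourseDecrease(cfg, "control", 1000), 0.30)
  expect_error(generateTimecourse(cfg, conditions = "control", times = -5),
               "non-negative")
})

test_that("an all-zero decrease schedule leaves time points exchangeable", {
  cfg <- smallConfig(n = 2000, seed = 15,
                     timecourse = list(control = list(
                       times = c(0, 60, 120), decrease = c(0, 0, 0))))
  tc <- generateTimecourse(cfg, conditions = "control")
  d0 <- tc$true_diameter[tc$time_min == 0]
  d2 <- tc$true_diameter[tc$time_min == 120]
  expect_gt(t.test(d0, d2)$p.value, 0.05)
})

test_that("particle tables survive a write/read round trip", {
  cfg <- smallConfig(n = 60, seed = 16)
  pop <- generatePopulation(cfg, conditions = "control")
  path <- tempfile(fileext = ".csv")
  writeParticles(pop, path)
  back <- readParticles(path)
  expect_equal(back$observed_protrusions, pop$observed_protrusions)
  expect_equal(back$diameter_long, pop$diameter_long, tolerance = 1e-12)
  expect_identical(bindingTableAsData(tabulateBinding(back)),
                   bindingTableAsData(tabulateBinding(pop)))
})

test_that("schema violations are reported with row addresses", {
  rec <- handBuiltRecords()
  bad <- rec; bad$diameter_long[3] <- -1
  expect_error(validateParticles(bad), "row\\(s\\) 3")
  bad <- rec; bad$ternary_partner[1] <- "L9"  # ternary but zero protrusions
  expect_error(validateParticles(bad), "ternary_partner")
  bad <- rec[, setdiff(names(rec), "diameter_perp")]
  expect_error(validateParticles(bad), "diameter_perp")
  expect_error(validateParticles(rec[0, ]), "empty")
})
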