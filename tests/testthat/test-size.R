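test_that("geometric-mean diameter is exact and below the arithmetic mean", {
  expect_equal(geometricMeanDiameter(12, 12), 12)
  expect_equal(geometricMeanDiameter(9, 16), 12)
  expect_equal(geometricMeanDiameter(24.8, 23.1), 23.935, tolerance = 1e-4)
  expect_error(geometricMeanDiameter(0, 10), "positive")
  # AM-GM with equality iff the axes agree
  set.seed(61)
  a <- runif(50, 5, 40); b <- runif(50, 5, 40)
  gm <- geometricMeanDiameter(a, b)
  expect_true(all(gm <= (a + b) / 2 + 1e-12))
  expect_true(all((gm == (a + b) / 2) == (abs(a - b) < 1e-12)))
})

test_that("histograms use left-closed 0.5 nm bins anchored on the lattice", {
  h <- buildHistogram(10.0)
  expect_equal(histogramBreaks(h), c(10.0, 10.5))
  expect_identical(histogramCounts(h), 1L)
  h <- buildHistogram(c(10.0, 10.49, 10.5))
  expect_equal(histogramBreaks(h), c(10.0, 10.5, 11.0))
  expect_identical(histogramCounts(h), c(2L, 1L))
  # anchoring: left edge is floor(min / width) * width
  h <- buildHistogram(c(7.3, 9.1), binWidth = 0.5)
  expect_equal(histogramBreaks(h)[1], 7.0)
  expect_equal(diff(histogramBreaks(h)), rep(0.5, length(histogramCounts(h))))
  # conservation on a simulated population
  pop <- generatePopulation(smallConfig(n = 300, seed = 62),
                            conditions = "control", classes = "HDL")
  d <- geometricMeanDiameter(pop$diameter_long, pop$diameter_perp)
  expect_equal(sum(histogramCounts(buildHistogram(d))), 300L)
  expect_error(buildHistogram(numeric(0)), "empty")
})

test_that("polynomial smoothing annotates without touching counts", {
  # counts exactly on a degree-2 polynomial are reproduced by a degree-6 fit
  counts <- as.integer((seq_len(11) - 6)^2 + 2)  # quadratic in the midpoint
  h <- new("DiameterHistogram",
           breaks = seq(10, 15.5, by = 0.5), counts = counts)
  hs <- smoothHistogram(h, degree = 6)
  expect_identical(histogramCounts(hs), counts)
  expect_lt(hs@rss, 1e-12)
  expect_equal(hs@fitted, as.numeric(counts), tolerance = 1e-6)
  expect_length(smoothingCoefficients(hs), 7)
  # fallback: 4 occupied bins cannot support degree 6
  h4 <- new("DiameterHistogram", breaks = seq(10, 12, by = 0.5),
            counts = c(2L, 5L, 4L, 1L))
  expect_warning(hs4 <- smoothHistogram(h4, degree = 6), "reduced to 3")
  expect_equal(hs4@degree, 3)
  # deterministic across repeat fits
  pop <- generatePopulation(smallConfig(n = 400, seed = 63),
                            conditions = "control", classes = "HDL")
  d <- geometricMeanDiameter(pop$diameter_long, pop$diameter_perp)
  f1 <- smoothHistogram(buildHistogram(d))
  f2 <- smoothHistogram(buildHistogram(d))
  expect_identical(f1@coefficients, f2@coefficients)
})

test_that("diameter summaries report n, mean, sd and percent change", {
  rec <- handBuiltRecords()
  s <- summarizeDiameters(rec, by = c("class", "condition"),
                          percentChange = FALSE)
  expect_equal(s$n, 6L)
  expect_equal(s$mean_diameter, 12)
  expect_equal(s$sd_diameter, 0)

  # hand-built two-time-point percent change: 12.0 -> 9.96 is -17%
  rec2 <- rbind(rec, transform(rec, time_min = 40,
                               diameter_long = 9.96, diameter_perp = 9.96,
                               particle_id = paste0(particle_id, "b")))
  s2 <- summarizeDiameters(rec2)
  expect_equal(s2$percent_change_from_t0[s2$time_min == 0], 0)
  expect_equal(s2$percent_change_from_t0[s2$time_min == 40], -17)

  # missing reference group
  rec3 <- transform(rec, time_min = 40)
  expect_error(summarizeDiameters(rec3), "time-0")
})

test_that("summaries recover configured class means without noise", {
  cfg <- simulationConfig(nParticles = 4000L, seed = 64, noiseSd = 0,
                          ternary = list(), timecourse = list())
  pop <- generatePopulation(cfg, conditions = "control")
  s <- summarizeDiameters(pop, by = c("class", "condition"),
                          percentChange = FALSE)
  for (cls in c("HDL", "LDL", "VLDL")) {
    row <- cfg@classes[cfg@classes$name == cls, ]
    got <- s[s$class == cls, ]
    expect_lt(abs(got$mean_diameter - row$diameter_mean),
              4 * row$diameter_sd / sqrt(4000))
    expect_lt(abs(got$sd_diameter - row$diameter_sd), 0.15 * row$diameter_sd)
  }
})

test_that("timecourse percent decreases are recovered at scale", {
  cfg <- smallConfig(n = 5000, seed = 65)
  tc <- generateTimecourse(cfg, conditions = "control")
  s <- summarizeDiameters(tc)
  for (t in c(40, 120, 480)) {
    truth <- -100 * timecourseDecrease(cfg, "control", t)
    got <- s$percent_change_from_t0[s$time_min == t]
    expect_lt(abs(got - truth), 1.5)  # percent points at n = 5000
  }
})
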