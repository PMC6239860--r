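# shared fixture builders -- fixtures are generated in code, never stored

smallConfig <- function(n = 150, seed = 1, ...) {
  simulationConfig(nParticles = n, seed = seed, ...)
}

# single-class two-condition design used for calibration / power checks
twoArmConfig <- function(pA, pB, n = 400, seed = 1) {
  simulationConfig(
    classes = data.frame(name = "HDL", diameter_mean = 12.28,
                         diameter_sd = 1.91, stringsAsFactors = FALSE),
    propensities = data.frame(condition = c("A", "B"), class = "HDL",
                              propensity = c(pA, pB),
                              stringsAsFactors = FALSE),
    multiplicity = list(HDL = c("1" = 0.8, "2" = 0.15, "3" = 0.05)),
    ternary = list(), timecourse = list(),
    nParticles = n, seed = seed)
}

# hand-built six-particle table from the tabulation example:
# observed protrusion counts {0, 0, 1, 1, 2, 1(ternary)}
handBuiltRecords <- function() {
  data.frame(
    particle_id = sprintf("p%d", 1:6),
    class = "HDL", condition = "control", time_min = 0,
    diameter_long = 12, diameter_perp = 12,
    observed_protrusions = c(0L, 0L, 1L, 1L, 2L, 1L),
    ternary_partner = c(NA, NA, NA, NA, NA, "L1"),
    stringsAsFactors = FALSE)
}

# independent volume-conservation oracle for the penetration model:
# diameter of a sphere holding the original sphere's volume plus an
# inserted cylinder of diameter d and length L
volumeOracleDiameter <- function(D, L, d) {
  vol <- pi * D^3 / 6 + pi * d^2 * L / 4
  (6 * vol / pi)^(1 / 3)
}

# closed-form 2x2 chi-square, optionally Yates-corrected (hand formula)
handChiSquare <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
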