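#' Parameter-recovery study on synthetic populations
#'
#' Repeatedly generates populations under the configured truths and checks
#' that the package's estimators recover them: the visibility-corrected
#' bound fraction against each configured HDL binding propensity, the
#' ternary fractions against their configured control targets, and the
#' time-course percent diameter decreases against the configured schedule.
#' Each estimate carries a 95\% confidence interval (Wald for binomial
#' fractions, delta-method for the mean-diameter ratio); \code{covered}
#' records whether the truth lies inside it.
#'
#' @param nSeeds number of independent replicate seeds.
#' @param nParticles particles per arm in each replicate.
#' @param baseSeed first seed; replicate \code{i} uses
#'   \code{baseSeed + i - 1}.
#' @param config template configuration (defaults to the study conditions);
#'   its seed and particle count are overridden per replicate.
#' @return data.frame with one row per (parameter, seed):
#'   \code{parameter}, \code{seed}, \code{truth}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{covered}.
#' @examples
#' rec <- assessRecovery(nSeeds = 3, nParticles = 1000, baseSeed = 42)
#' mean(rec$covered)
#' @export
assessRecovery <- function(nSeeds = 100L, nParticles = 5000L,
                           baseSeed = 1L, config = simulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  z <- 1.959964
  rows <- list()
  add <- function(parameter, seed, truth, estimate, se) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, seed = seed, truth = truth,
      estimate = estimate, lower = estimate - z * se,
      upper = estimate + z * se,
      covered = abs(estimate - truth) <= z * se,
      stringsAsFactors = FALSE)
  }
  hdlRow <- .classRow(config, "HDL")
  geomHDL <- RodSphereGeometry(hdlRow$diameter_mean,
                               rodLength = config@rodLength)
  p1 <- visibilityProbability(hdlRow$diameter_mean, config@rodLength)
  pDet <- detectionProbability(p1, config@multiplicity[["HDL"]])
  pr <- config@propensities
  hdlProps <- pr[pr$class == "HDL", ]
  tn <- config@ternary
  tc <- config@timecourse[["control"]]

  for (i in seq_len(nSeeds)) {
    cfg <- config
    cfg@nParticles <- as.integer(nParticles)
    cfg@seed <- as.integer(baseSeed + i - 1L)

    ## corrected binding-propensity recovery, one parameter per condition
    pop <- generatePopulation(cfg, classes = "HDL")
    tabs <- tabulateBinding(pop)
    for (j in seq_len(nrow(hdlProps))) {
      cond <- hdlProps$condition[j]
      tb <- tabs[[paste("HDL", cond, sep = ".")]]
      fo <- boundFraction(tb)
      fc <- suppressWarnings(
        correctedBoundFraction(tb, geomHDL, cfg@multiplicity[["HDL"]]))
      se <- sqrt(fo * (1 - fo) / tb@nTotal) / pDet
      add(paste0("binding_HDL_", cond), cfg@seed, hdlProps$propensity[j],
          fc, se)
    }

    ## ternary fractions (control incubation)
    if (length(tn)) {
      tpop <- generateTernaryPopulation(cfg, conditions = "control")
      tt <- tabulateBinding(tpop)
      fr <- ternaryFractions(tt[["HDL.control"]], tt[["LDL.control"]])
      nH <- tt[["HDL.control"]]@nTotal
      nL <- tt[["LDL.control"]]@nTotal
      truthH <- tn$hdl_propensity[["control"]] *
        min(1, tn$probability * tn$modulation[["control"]])
      seH <- sqrt(truthH * (1 - truthH) / nH)
      add("ternary_fraction_HDL", cfg@seed, truthH, fr[["hdl"]], seH)
      add("ternary_fraction_LDL", cfg@seed, truthH * nH / nL, fr[["ldl"]],
          seH * nH / nL)
    }

    ## time-course percent decreases (control schedule, nonzero entries)
    if (!is.null(tc)) {
      times <- tc$times[tc$decrease > 0 | tc$times == 0]
      pop <- generateTimecourse(cfg, conditions = "control", times = times)
      sm <- summarizeDiameters(pop)
      t0 <- sm[sm$time_min == 0, ]
      for (t in setdiff(times, 0)) {
        truth <- timecourseDecrease(cfg, "control", t)
        if (truth == 0) next
        st <- sm[sm$time_min == t, ]
        ratio <- st$mean_diameter / t0$mean_diameter
        seRatio <- ratio * sqrt(
          (st$sd_diameter / st$mean_diameter)^2 / st$n +
          (t0$sd_diameter / t0$mean_diameter)^2 / t0$n)
        add(paste0("diameter_decrease_", t, "min"), cfg@seed,
            truth, 1 - ratio, seRatio)
      }
    }
  }
  do.call(rbind, rows)
}
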