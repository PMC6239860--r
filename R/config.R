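#' Generative specification of a synthetic particle population
#'
#' Full description of the population the synthetic generator draws:
#' per-class diameter distributions, per-condition binding propensities,
#' protrusion-multiplicity distributions, the ternary (HDL-CETP-LDL
#' bridging) experiment, the lipid-transfer time course, measurement noise
#' and the RNG seed. Defaults reproduce the conditions of the negative-stain
#' EM counting study this package models: HDL 12.28 +/- 1.91 nm, LDL
#' 23.6 +/- 1.3 nm, VLDL 38.28 +/- 7.12 nm; HDL binding 9.9\% (control) to
#' 50.5\% (Torcetrapib); ternary fractions 12.2\% (per HDL) / 19.5\%
#' (per LDL) in the control; HDL diameter decreases of 17/21/30\% at
#' 40 min / 2 h / 8 h in the control.
#'
#' @slot classes data.frame(name, diameter_mean, diameter_sd) in nm.
#' @slot propensities data.frame(condition, class, propensity) — probability
#'   that a particle of that class is CETP-bound under that condition.
#' @slot multiplicity named list (by class) of named numeric probability
#'   vectors over CETPs per bound particle ("1", "2", "3" = three or more,
#'   drawn as three).
#' @slot ternary list configuring the bridging experiment (may be empty):
#'   \code{probability} (bridge probability for a bound HDL),
#'   \code{modulation} (named per-condition multiplicative factor on that
#'   probability), \code{hdl_propensity} (named per-condition HDL binding
#'   propensity in the ternary incubation), \code{ldl_to_hdl} (LDL arm size
#'   as a fraction of the HDL arm).
#' @slot timecourse named list (by condition) with \code{times} (minutes)
#'   and \code{decrease} (fractional HDL diameter decrease at each time).
#' @slot rodLength numeric(1), nm; CETP protrusion length (default 8).
#' @slot noiseSd numeric(1), nm; SD of independent measurement noise on each
#'   of the two perpendicular diameter readings.
#' @slot nParticles integer(1); particles per class per condition.
#' @slot seed integer(1) RNG seed.
#' @seealso [simulationConfig()], [generatePopulation()],
#'   [generateTernaryPopulation()], [generateTimecourse()].
#' @export
setClass("SimulationConfig",
  representation(
    classes      = "data.frame",
    propensities = "data.frame",
    multiplicity = "list",
    ternary      = "list",
    timecourse   = "list",
    rodLength    = "numeric",
    noiseSd      = "numeric",
    nParticles   = "integer",
    seed         = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  cl <- object@classes
  if (!all(c("name", "diameter_mean", "diameter_sd") %in% names(cl)))
    msg <- c(msg, "classes needs columns name, diameter_mean, diameter_sd")
  else {
    if (any(cl$diameter_mean <= 0)) msg <- c(msg, "diameter_mean must be > 0")
    if (any(cl$diameter_sd < 0)) msg <- c(msg, "diameter_sd must be >= 0")
    if (anyDuplicated(cl$name)) msg <- c(msg, "duplicate class names")
  }
  pr <- object@propensities
  if (!all(c("condition", "class", "propensity") %in% names(pr)))
    msg <- c(msg, "propensities needs columns condition, class, propensity")
  else {
    if (any(pr$propensity < 0 | pr$propensity > 1))
      msg <- c(msg, "propensity values must be in [0, 1]")
    if (!all(pr$class %in% cl$name))
      msg <- c(msg, "propensities refer to unknown classes")
  }
  for (k in names(object@multiplicity)) {
    m <- object@multiplicity[[k]]
    if (any(m < 0) || abs(sum(m) - 1) > 1e-8)
      msg <- c(msg, paste0("multiplicity[", k, "] must be a probability ",
                           "distribution summing to 1"))
  }
  if (length(object@ternary)) {
    tn <- object@ternary
    if (!is.null(tn$probability) &&
        (tn$probability < 0 || tn$probability > 1))
      msg <- c(msg, "ternary$probability must be in [0, 1]")
    if (!is.null(tn$hdl_propensity) &&
        any(tn$hdl_propensity < 0 | tn$hdl_propensity > 1))
      msg <- c(msg, "ternary$hdl_propensity values must be in [0, 1]")
    if (!is.null(tn$modulation) && any(tn$modulation <= 0))
      msg <- c(msg, "ternary$modulation must be > 0")
    if (!is.null(tn$ldl_to_hdl) && tn$ldl_to_hdl <= 0)
      msg <- c(msg, "ternary$ldl_to_hdl must be > 0")
  }
  for (k in names(object@timecourse)) {
    tc <- object@timecourse[[k]]
    if (is.null(tc$times) || is.null(tc$decrease) ||
        length(tc$times) != length(tc$decrease))
      msg <- c(msg, paste0("timecourse[", k, "] needs equal-length times ",
                           "and decrease"))
    else {
      if (any(tc$times < 0) || is.unsorted(tc$times, strictly = TRUE))
        msg <- c(msg, paste0("timecourse[", k, "] times must be ",
                             "non-negative and strictly increasing"))
      if (any(tc$decrease < 0 | tc$decrease >= 1))
        msg <- c(msg, paste0("timecourse[", k, "] decrease must be in [0, 1)"))
    }
  }
  if (object@rodLength < 0) msg <- c(msg, "rodLength must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nParticles < 1L) msg <- c(msg, "nParticles must be >= 1")
  if (is.na(object@seed)) msg <- c(msg, "seed must be an integer")
  if (length(msg)) msg else TRUE
})

.defaultClasses <- function() {
  data.frame(
    name = c("HDL", "LDL", "VLDL"),
    diameter_mean = c(12.28, 23.6, 38.28),
    diameter_sd = c(1.91, 1.3, 7.12),
    stringsAsFactors = FALSE
  )
}

.defaultPropensities <- function() {
  conditions <- c("control", "Torcetrapib", "Dalcetrapib", "Anacetrapib")
  data.frame(
    condition = rep(conditions, each = 3),
    class = rep(c("HDL", "LDL", "VLDL"), times = 4),
    propensity = c(
      0.099, 0.129, 0.351,   # control
      0.505, 0.218, 0.463,   # Torcetrapib
      0.292, 0.226, 0.470,   # Dalcetrapib
      0.431, 0.234, 0.500    # Anacetrapib
    ),
    stringsAsFactors = FALSE
  )
}

.defaultMultiplicity <- function() {
  list(
    HDL  = c("1" = 0.80, "2" = 0.15, "3" = 0.05),
    LDL  = c("1" = 0.85, "2" = 0.12, "3" = 0.03),
    VLDL = c("1" = 0.40, "2" = 0.35, "3" = 0.25)
  )
}

.defaultTernary <- function() {
  list(
    probability = 1.0,
    modulation = c(control = 1, Torcetrapib = 1, Dalcetrapib = 1,
                   Anacetrapib = 1),
    hdl_propensity = c(control = 0.122, Torcetrapib = 0.069,
                       Dalcetrapib = 0.097, Anacetrapib = 0.0651),
    ldl_to_hdl = 0.626
  )
}

.defaultTimecourse <- function() {
  slow <- list(times = c(0, 15, 40, 120, 480),
               decrease = c(0, 0, 0.17, 0.21, 0.30))
  fast <- list(times = c(0, 15, 40, 120, 480),
               decrease = c(0, 0, 0, 0.10, 0.25))
  list(control = slow, Dalcetrapib = slow,
       Torcetrapib = fast, Anacetrapib = fast)
}

#' Build a simulation configuration
#'
#' Every argument defaults to the study conditions documented in
#' [SimulationConfig-class]; override any subset.
#'
#' @param classes data.frame(name, diameter_mean, diameter_sd).
#' @param propensities data.frame(condition, class, propensity).
#' @param multiplicity named list of per-class multiplicity distributions.
#' @param ternary list for the bridging experiment, or \code{list()} to
#'   disable it.
#' @param timecourse named per-condition list, or \code{list()} to disable.
#' @param rodLength CETP protrusion length in nm.
#' @param noiseSd diameter measurement noise SD in nm.
#' @param nParticles particles per class per condition.
#' @param seed integer RNG seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nParticles = 100, seed = 7)
#' cfg
#' @export
simulationConfig <- function(classes = .defaultClasses(),
                             propensities = .defaultPropensities(),
                             multiplicity = .defaultMultiplicity(),
                             ternary = .defaultTernary(),
                             timecourse = .defaultTimecourse(),
                             rodLength = 8,
                             noiseSd = 0.3,
                             nParticles = 400L,
                             seed = 1L) {
  new("SimulationConfig",
      classes = classes, propensities = propensities,
      multiplicity = multiplicity, ternary = ternary,
      timecourse = timecourse, rodLength = rodLength, noiseSd = noiseSd,
      nParticles = as.integer(nParticles), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      nrow(object@classes), "classes x",
      length(unique(object@propensities$condition)), "conditions,",
      object@nParticles, "particles each; seed", object@seed, "\n")
  cat("  rod length", object@rodLength, "nm; measurement noise sd",
      object@noiseSd, "nm\n")
  if (length(object@ternary)) cat("  ternary bridging experiment enabled\n")
  if (length(object@timecourse))
    cat("  timecourse for:", paste(names(object@timecourse), collapse = ", "),
        "\n")
  invisible(object)
})

#' @rdname simulationConfig
#' @param config a \code{SimulationConfig}.
#' @return \code{configAsList()} returns a plain nested list suitable for
#'   YAML/JSON serialisation.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  list(
    classes = lapply(seq_len(nrow(config@classes)), function(i)
      as.list(config@classes[i, , drop = FALSE])),
    propensities = lapply(seq_len(nrow(config@propensities)), function(i)
      as.list(config@propensities[i, , drop = FALSE])),
    multiplicity = lapply(config@multiplicity, as.list),
    ternary = if (length(config@ternary)) {
      tn <- config@ternary
      list(probability = tn$probability,
           modulation = as.list(tn$modulation),
           hdl_propensity = as.list(tn$hdl_propensity),
           ldl_to_hdl = tn$ldl_to_hdl)
    } else NULL,
    timecourse = config@timecourse,
    rod_length = config@rodLength,
    measurement_noise_sd = config@noiseSd,
    n_particles = config@nParticles,
    seed = config@seed
  )
}

#' Read / write a simulation configuration as YAML
#'
#' The on-disk schema mirrors [configAsList()]: top-level keys
#' \code{classes}, \code{propensities}, \code{multiplicity}, \code{ternary},
#' \code{timecourse}, \code{rod_length}, \code{measurement_noise_sd},
#' \code{n_particles}, \code{seed}. Omitted keys fall back to the package
#' defaults.
#'
#' @param path file path of a YAML configuration.
#' @return [SimulationConfig-class] object.
#' @export
readSimulationConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$classes))
    args$classes <- do.call(rbind, lapply(raw$classes, function(x)
      data.frame(name = x$name, diameter_mean = x$diameter_mean,
                 diameter_sd = x$diameter_sd, stringsAsFactors = FALSE)))
  if (!is.null(raw$propensities))
    args$propensities <- do.call(rbind, lapply(raw$propensities, function(x)
      data.frame(condition = x$condition, class = x$class,
                 propensity = x$propensity, stringsAsFactors = FALSE)))
  if (!is.null(raw$multiplicity))
    args$multiplicity <- lapply(raw$multiplicity, unlist)
  if (!is.null(raw$ternary)) {
    tn <- raw$ternary
    args$ternary <- list(
      probability = if (is.null(tn$probability)) 1 else tn$probability,
      modulation = unlist(tn$modulation),
      hdl_propensity = unlist(tn$hdl_propensity),
      ldl_to_hdl = if (is.null(tn$ldl_to_hdl)) 0.626 else tn$ldl_to_hdl)
  }
  if (!is.null(raw$timecourse))
    args$timecourse <- lapply(raw$timecourse, function(tc)
      list(times = unlist(tc$times), decrease = unlist(tc$decrease)))
  for (k in c("rod_length", "measurement_noise_sd", "n_particles", "seed")) {
    if (!is.null(raw[[k]]))
      args[[c(rod_length = "rodLength", measurement_noise_sd = "noiseSd",
              n_particles = "nParticles", seed = "seed")[[k]]]] <- raw[[k]]
  }
  do.call(simulationConfig, args)
}

#' @rdname readSimulationConfig
#' @param config a [SimulationConfig-class] object.
#' @export
writeSimulationConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}
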