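## Synthetic particle populations with the statistical structure of
## annotated negative-stain micrographs: per-class diameter distributions,
## per-condition binding propensities, geometric (not analytic) occlusion of
## protrusions, measurement noise, ternary bridging and a shrinkage
## time course. The analytic visibility probability is deliberately NOT used
## inside the generator, so it can serve as an independent oracle in tests.

.PARTICLE_COLUMNS <- c("particle_id", "class", "condition", "time_min",
                       "diameter_long", "diameter_perp",
                       "observed_protrusions", "ternary_partner")
.TRUTH_COLUMNS <- c("true_diameter", "true_protrusions", "attachment_angles")

## truncated normal by resampling; lower bound keeps diameters physical
.truncNorm <- function(n, mean, sd, lower = 1) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

.drawMultiplicity <- function(n, dist) {
  if (n == 0L) return(integer(0))
  k <- as.integer(names(dist))
  if (length(k) == 1L) rep(k, n) else sample(k, n, replace = TRUE, prob = dist)
}

## Geometric silhouette test for each attachment: polar angle theta of the
## attachment point relative to the viewing axis has cos(theta) ~ U(-1, 1)
## for a uniform point on the sphere; the protrusion tip clears the
## silhouette iff sin(theta) > d / (d + 2 l). Zero margin: a tip exactly on
## the silhouette is invisible.
.observeAttachments <- function(trueDiameter, nAttach, rodLength) {
  total <- sum(nAttach)
  observed <- integer(length(nAttach))
  angles <- rep(NA_character_, length(nAttach))
  if (total == 0L) return(list(observed = observed, angles = angles))
  idx <- rep(seq_along(nAttach), nAttach)
  cosTheta <- runif(total, -1, 1)
  sinTheta <- sqrt(1 - cosTheta^2)
  thr <- trueDiameter[idx] / (trueDiameter[idx] + 2 * rodLength)
  visible <- sinTheta > thr
  obs <- tapply(visible, factor(idx, levels = seq_along(nAttach)), sum)
  observed <- as.integer(ifelse(is.na(obs), 0L, obs))
  theta <- acos(cosTheta)
  ang <- tapply(theta, factor(idx, levels = seq_along(nAttach)),
                function(a) paste(sprintf("%.6f", a), collapse = ";"))
  angles <- as.character(ang)
  list(observed = observed, angles = angles)
}

.measure <- function(trueDiameter, noiseSd) {
  n <- length(trueDiameter)
  one <- function() {
    m <- trueDiameter + rnorm(n, 0, noiseSd)
    bad <- which(m <= 0)
    while (length(bad)) {
      m[bad] <- trueDiameter[bad] + rnorm(length(bad), 0, noiseSd)
      bad <- bad[m[bad] <= 0]
    }
    m
  }
  list(long = one(), perp = one())
}

.classRow <- function(config, className) {
  i <- match(className, config@classes$name)
  if (is.na(i)) stop("unknown class: ", className, call. = FALSE)
  config@classes[i, ]
}

.emptyParticles <- function() {
  df <- data.frame(
    particle_id = character(0), class = character(0),
    condition = character(0), time_min = numeric(0),
    diameter_long = numeric(0), diameter_perp = numeric(0),
    observed_protrusions = integer(0), ternary_partner = character(0),
    true_diameter = numeric(0), true_protrusions = integer(0),
    attachment_angles = character(0), stringsAsFactors = FALSE)
  df
}

.makeRecords <- function(className, condition, timeMin, trueD, nAttach,
                         config, idPrefix, forcedVisible = 0L,
                         partner = NULL) {
  n <- length(trueD)
  obs <- .observeAttachments(trueD, pmax(nAttach - forcedVisible, 0L),
                             config@rodLength)
  observed <- obs$observed + forcedVisible
  meas <- .measure(trueD, config@noiseSd)
  data.frame(
    particle_id = sprintf("%s_%05d", idPrefix, seq_len(n)),
    class = className, condition = condition, time_min = timeMin,
    diameter_long = meas$long, diameter_perp = meas$perp,
    observed_protrusions = as.integer(observed),
    ternary_partner = if (is.null(partner)) NA_character_ else partner,
    true_diameter = trueD, true_protrusions = as.integer(nAttach),
    attachment_angles = obs$angles,
    stringsAsFactors = FALSE)
}

#' Monte Carlo estimate of the protrusion visibility probability
#'
#' Draws attachment points uniformly on a sphere and applies the silhouette
#' test (tip visible iff \code{sin(theta) > d / (d + 2 l)} with \code{theta}
#' the polar angle from the viewing axis). This is the simulation
#' counterpart of [visibilityProbability()] and agrees with it to Monte
#' Carlo error.
#'
#' @param sphereDiameter sphere diameter in nm, > 0.
#' @param rodLength protrusion length in nm, >= 0.
#' @param nSamples number of attachment draws, >= 1.
#' @param seed integer RNG seed.
#' @return visible fraction in [0, 1].
#' @examples
#' simulateVisibleFraction(10, 8, 1e5, seed = 1)  # ~0.923
#' @export
simulateVisibleFraction <- function(sphereDiameter, rodLength, nSamples,
                                    seed = 1L) {
  .checkPositive(sphereDiameter, "sphereDiameter", strict = TRUE)
  .checkPositive(rodLength, "rodLength", strict = FALSE)
  if (nSamples < 1) stop("nSamples must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  cosTheta <- runif(nSamples, -1, 1)
  sinTheta <- sqrt(1 - cosTheta^2)
  mean(sinTheta > sphereDiameter / (sphereDiameter + 2 * rodLength))
}

#' Generate a synthetic binary-complex particle population
#'
#' For every class x condition pair in the configuration, draws
#' \code{nParticles} particles: a true diameter from the truncated normal
#' class distribution, a Bernoulli binding event with the configured
#' propensity, a protrusion multiplicity for bound particles, an independent
#' uniform attachment orientation per protrusion (observed protrusions are
#' those clearing the silhouette), and two noisy perpendicular diameter
#' measurements. Deterministic for a fixed config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param conditions optional character subset of conditions to generate.
#' @param classes optional character subset of classes to generate.
#' @return data.frame of particle records (one row per particle) with truth
#'   columns \code{true_diameter}, \code{true_protrusions},
#'   \code{attachment_angles}.
#' @examples
#' records <- generatePopulation(simulationConfig(nParticles = 50, seed = 2))
#' head(records)
#' @export
generatePopulation <- function(config, conditions = NULL, classes = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  pr <- config@propensities
  if (!is.null(conditions)) pr <- pr[pr$condition %in% conditions, ]
  if (!is.null(classes)) pr <- pr[pr$class %in% classes, ]
  if (!nrow(pr)) stop("no class x condition combinations selected",
                      call. = FALSE)
  out <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    cls <- .classRow(config, pr$class[i])
    n <- config@nParticles
    trueD <- .truncNorm(n, cls$diameter_mean, cls$diameter_sd)
    bound <- runif(n) < pr$propensity[i]
    k <- integer(n)
    mult <- config@multiplicity[[pr$class[i]]]
    if (is.null(mult)) mult <- c("1" = 1)
    k[bound] <- .drawMultiplicity(sum(bound), mult)
    out[[i]] <- .makeRecords(pr$class[i], pr$condition[i], 0, trueD, k,
                             config,
                             idPrefix = paste(pr$class[i], pr$condition[i],
                                              "b", sep = "_"))
  }
  do.call(rbind, out)
}

#' Generate a paired HDL/LDL population with ternary bridging
#'
#' Emulates the ternary incubation (CETP with HDL and LDL simultaneously):
#' HDL particles bind CETP with the ternary-context propensity for their
#' condition; each bound HDL bridges an LDL particle with probability
#' \code{probability x modulation[condition]}. A bridge contributes one
#' protrusion to each partner, is always observable (an annotator only
#' scores a ternary complex when the bridge is visible), and
#' cross-references the two records through \code{ternary_partner}. The LDL
#' arm holds \code{round(ldl_to_hdl x nParticles)} particles.
#'
#' @inheritParams generatePopulation
#' @return data.frame of HDL and LDL particle records.
#' @examples
#' cfg <- simulationConfig(nParticles = 200, seed = 3)
#' tern <- generateTernaryPopulation(cfg, conditions = "control")
#' table(tern$class, !is.na(tern$ternary_partner))
#' @export
generateTernaryPopulation <- function(config, conditions = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  tn <- config@ternary
  if (!length(tn))
    stop("ternary specification missing from config", call. = FALSE)
  set.seed(config@seed + 1L)
  conds <- names(tn$hdl_propensity)
  if (!is.null(conditions)) conds <- intersect(conds, conditions)
  if (!length(conds)) stop("no ternary conditions selected", call. = FALSE)
  hdl <- .classRow(config, "HDL")
  ldl <- .classRow(config, "LDL")
  out <- list()
  for (cond in conds) {
    nH <- config@nParticles
    nL <- max(1L, as.integer(round(tn$ldl_to_hdl * nH)))
    mod <- if (!is.null(tn$modulation) && cond %in% names(tn$modulation))
      tn$modulation[[cond]] else 1
    pBridge <- min(1, tn$probability * mod)

    trueDH <- .truncNorm(nH, hdl$diameter_mean, hdl$diameter_sd)
    bound <- runif(nH) < tn$hdl_propensity[[cond]]
    k <- integer(nH)
    k[bound] <- .drawMultiplicity(sum(bound), config@multiplicity[["HDL"]])
    bridge <- bound & (runif(nH) < pBridge)
    if (sum(bridge) > nL) {
      warning("more bridged HDL than LDL particles; capping at ", nL)
      drop <- sample(which(bridge), sum(bridge) - nL)
      bridge[drop] <- FALSE
    }
    ldlIds <- sprintf("LDL_%s_t_%05d", cond, seq_len(nL))
    hdlIds <- sprintf("HDL_%s_t_%05d", cond, seq_len(nH))
    partnerH <- rep(NA_character_, nH)
    partnerH[bridge] <- sample(ldlIds, sum(bridge))

    recH <- .makeRecords("HDL", cond, 0, trueDH, k, config,
                         idPrefix = paste("HDL", cond, "t", sep = "_"),
                         forcedVisible = as.integer(bridge),
                         partner = partnerH)
    trueDL <- .truncNorm(nL, ldl$diameter_mean, ldl$diameter_sd)
    partnerL <- rep(NA_character_, nL)
    partnerL[match(partnerH[bridge], ldlIds)] <- hdlIds[bridge]
    kL <- as.integer(!is.na(partnerL))
    recL <- .makeRecords("LDL", cond, 0, trueDL, kL, config,
                         idPrefix = paste("LDL", cond, "t", sep = "_"),
                         forcedVisible = kL, partner = partnerL)
    out[[cond]] <- rbind(recH, recL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fractional HDL diameter decrease at an arbitrary time
#'
#' Piecewise-linear interpolation of the configured (time, decrease) points
#' for one condition; times beyond the configured range are clamped to the
#' nearest endpoint.
#'
#' @param config a [SimulationConfig-class] with a timecourse spec.
#' @param condition condition name.
#' @param time time(s) in minutes.
#' @return fractional decrease(s) in [0, 1).
#' @export
timecourseDecrease <- function(config, condition, time) {
  tc <- config@timecourse[[condition]]
  if (is.null(tc))
    stop("no timecourse spec for condition ", condition, call. = FALSE)
  approx(tc$times, tc$decrease, xout = time, rule = 2)$y
}

#' Generate HDL populations along the lipid-transfer time course
#'
#' At each time point the HDL diameter mean is scaled by
#' \code{1 - decrease(t)} for the condition (time 0 uses the unscaled mean)
#' and a fresh population is sampled; binding uses the condition's HDL
#' propensity.
#'
#' @inheritParams generatePopulation
#' @param times optional numeric times (minutes); defaults to each
#'   condition's configured time grid.
#' @return data.frame of HDL particle records with \code{time_min} set.
#' @examples
#' cfg <- simulationConfig(nParticles = 100, seed = 4)
#' tc <- generateTimecourse(cfg, conditions = "control")
#' aggregate(true_diameter ~ time_min, tc, mean)
#' @export
generateTimecourse <- function(config, conditions = NULL, times = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!length(config@timecourse))
    stop("timecourse specification missing from config", call. = FALSE)
  set.seed(config@seed + 2L)
  conds <- names(config@timecourse)
  if (!is.null(conditions)) conds <- intersect(conds, conditions)
  if (!length(conds)) stop("no timecourse conditions selected", call. = FALSE)
  hdl <- .classRow(config, "HDL")
  pr <- config@propensities
  out <- list()
  for (cond in conds) {
    tGrid <- if (is.null(times)) config@timecourse[[cond]]$times else times
    if (any(tGrid < 0)) stop("times must be non-negative", call. = FALSE)
    prop <- pr$propensity[pr$condition == cond & pr$class == "HDL"]
    if (!length(prop)) prop <- 0
    for (t in tGrid) {
      dec <- timecourseDecrease(config, cond, t)
      n <- config@nParticles
      trueD <- .truncNorm(n, hdl$diameter_mean * (1 - dec), hdl$diameter_sd)
      bound <- runif(n) < prop
      k <- integer(n)
      k[bound] <- .drawMultiplicity(sum(bound), config@multiplicity[["HDL"]])
      out[[paste(cond, t)]] <-
        .makeRecords("HDL", cond, t, trueD, k, config,
                     idPrefix = sprintf("HDL_%s_t%g", cond, t))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Validate a particle-record table
#'
#' Checks the documented schema: required columns, positive diameters,
#' non-negative integer protrusion counts, ternary partners implying at
#' least one observed protrusion, and (when truth columns are present)
#' observed counts not exceeding true counts. Errors name the offending
#' rows.
#'
#' @param records data.frame of particle records.
#' @return the records, invisibly, when valid.
#' @export
validateParticles <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty particle table", call. = FALSE)
  missing <- setdiff(.PARTICLE_COLUMNS, names(records))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  .rowErr <- function(bad, what) {
    if (length(bad))
      stop(what, " at row(s) ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  for (col in c("diameter_long", "diameter_perp")) {
    if (!is.numeric(records[[col]]))
      stop("column ", col, " must be numeric", call. = FALSE)
    .rowErr(which(!is.finite(records[[col]]) | records[[col]] <= 0),
            paste("non-positive", col))
  }
  op <- records$observed_protrusions
  if (!is.numeric(op)) stop("observed_protrusions must be numeric",
                            call. = FALSE)
  .rowErr(which(is.na(op) | op < 0 | op != floor(op)),
          "invalid observed_protrusions")
  tern <- !is.na(records$ternary_partner) & records$ternary_partner != ""
  .rowErr(which(tern & op < 1),
          "ternary_partner set with zero observed protrusions")
  if ("true_protrusions" %in% names(records)) {
    tp <- records$true_protrusions
    .rowErr(which(!is.na(tp) & op > tp),
            "observed_protrusions exceeds true_protrusions")
  }
  if ("true_diameter" %in% names(records))
    .rowErr(which(!is.na(records$true_diameter) & records$true_diameter <= 0),
            "non-positive true_diameter")
  invisible(records)
}

#' Write / read particle-record tables as delimited text
#'
#' Comma-separated, header row, UTF-8, '.' decimal point. Reading validates
#' the schema ([validateParticles()]); truth columns are optional.
#'
#' @param records data.frame of particle records.
#' @param path CSV file path.
#' @return \code{writeParticles} the path invisibly; \code{readParticles}
#'   the validated data.frame.
#' @export
writeParticles <- function(records, path) {
  validateParticles(records)
  write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname writeParticles
#' @export
readParticles <- function(path) {
  if (!file.exists(path)) stop("particle file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("particle_id" %in% names(df))
    df$particle_id <- as.character(df$particle_id)
  if ("ternary_partner" %in% names(df)) {
    df$ternary_partner <- as.character(df$ternary_partner)
    df$ternary_partner[df$ternary_partner == ""] <- NA_character_
  }
  validateParticles(df)
  df
}
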