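## Configuration-driven orchestration: simulate (or ingest) particle
## tables, run the binding and size analyses, and emit delimited-text
## tables plus a single machine-readable JSON report. Fully regenerable
## from config + seed.

#' Validated ingest of an annotated particle table
#'
#' Reads a delimited-text particle table (the schema written by
#' [writeParticles()]; truth columns optional, as for real annotated
#' micrograph counts) and validates it row by row.
#'
#' @param path CSV file path.
#' @return validated particle data.frame.
#' @export
ingestParticles <- function(path) readParticles(path)

#' Evaluate the geometric models for a set of configured geometries
#'
#' @param geometries either a YAML config path whose \code{geometry} key
#'   lists geometries (fields \code{sphere_diameter}, \code{rod_length},
#'   \code{rod_diameter}, \code{merged_length}), a data.frame with those
#'   columns, or a list of such lists. An empty set yields an empty table.
#' @param availableFraction surface fraction available to fused proteins
#'   (default 0.5).
#' @return data.frame, one row per geometry, with the visibility
#'   probability, correction percent, fusion surface fraction, maximum
#'   fused count and penetration diameter (see [geometrySummary()]).
#' @examples
#' evaluateGeometry(data.frame(sphere_diameter = 10, rod_length = 8,
#'                             rod_diameter = 2.5, merged_length = 5))
#' @export
evaluateGeometry <- function(geometries, availableFraction = 0.5) {
  if (is.character(geometries) && length(geometries) == 1L) {
    raw <- yaml::read_yaml(geometries)
    geometries <- raw$geometry
  }
  if (is.data.frame(geometries))
    geometries <- lapply(seq_len(nrow(geometries)), function(i)
      as.list(geometries[i, , drop = FALSE]))
  if (is.null(geometries) || length(geometries) == 0L)
    return(data.frame())
  do.call(rbind, lapply(geometries, function(g) {
    geom <- RodSphereGeometry(
      sphereDiameter = g$sphere_diameter,
      rodLength = if (is.null(g$rod_length)) 8 else g$rod_length,
      rodDiameter = if (is.null(g$rod_diameter)) 2.5 else g$rod_diameter,
      mergedLength = if (is.null(g$merged_length)) 5 else g$merged_length)
    geometrySummary(geom, availableFraction = availableFraction)
  }))
}

.classGeometries <- function(config) {
  lapply(seq_len(nrow(config@classes)), function(i)
    list(sphere_diameter = config@classes$diameter_mean[i],
         rod_length = config@rodLength,
         rod_diameter = 2.5, merged_length = 5))
}

## Analysis stage shared by runPipeline() and analyzeParticles():
## tabulate -> estimate -> compare -> summarize.
.analyze <- function(binary = NULL, ternary = NULL, timecourse = NULL,
                     config = NULL, control = "control") {
  res <- list()
  warningsSeen <- character(0)
  note <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (!is.null(binary)) {
    tabs <- tabulateBinding(binary)
    df <- bindingTableAsData(tabs)
    if (!is.null(config)) {
      df$corrected_bound_fraction <- vapply(seq_len(nrow(df)), function(i) {
        cls <- .classRow(config, df$class[i])
        geom <- RodSphereGeometry(cls$diameter_mean,
                                  rodLength = config@rodLength)
        note(correctedBoundFraction(tabs[[paste(df$class[i], df$condition[i],
                                                sep = ".")]],
                                    geom,
                                    config@multiplicity[[df$class[i]]]))
      }, numeric(1))
    }
    res$binding_tables <- df
    comps <- list()
    for (cls in unique(df$class)) {
      ctrlKey <- paste(cls, control, sep = ".")
      if (!ctrlKey %in% names(tabs)) next
      for (cond in setdiff(unique(df$condition[df$class == cls]), control)) {
        cr <- tryCatch(
          compareConditions(tabs[[paste(cls, cond, sep = ".")]],
                            tabs[[ctrlKey]], yates = TRUE),
          error = function(e) {
            # degenerate 2x2 (e.g. no bound particles anywhere): no
            # evidence of a difference
            warningsSeen <<- c(warningsSeen, conditionMessage(e))
            new("ComparisonResult", statistic = NA_real_, df = 1,
                pValue = 1, yates = TRUE, significant = FALSE)
          })
        comps[[length(comps) + 1L]] <- data.frame(
          class = cls, condition = cond, reference = control,
          chi_square = cr@statistic, df = as.integer(cr@df),
          p_value = cr@pValue, p_display = formatPValue(cr@pValue),
          yates = cr@yates, significant = cr@significant,
          stringsAsFactors = FALSE)
      }
    }
    if (length(comps)) res$comparisons <- do.call(rbind, comps)
  }
  if (!is.null(ternary)) {
    tt <- tabulateBinding(ternary)
    tf <- list()
    for (cond in unique(ternary$condition)) {
      hk <- paste("HDL", cond, sep = "."); lk <- paste("LDL", cond, sep = ".")
      if (!all(c(hk, lk) %in% names(tt))) next
      fr <- ternaryFractions(tt[[hk]], tt[[lk]])
      tf[[length(tf) + 1L]] <- data.frame(
        condition = cond, n_ternary = tt[[hk]]@nTernary,
        n_hdl = tt[[hk]]@nTotal, n_ldl = tt[[lk]]@nTotal,
        hdl_ternary_fraction = fr[["hdl"]],
        ldl_ternary_fraction = fr[["ldl"]], stringsAsFactors = FALSE)
    }
    if (length(tf)) res$ternary_fractions <- do.call(rbind, tf)
  }
  if (!is.null(timecourse)) {
    res$diameter_summaries <- summarizeDiameters(timecourse)
    hists <- list()
    for (cond in unique(timecourse$condition)) {
      sub <- timecourse[timecourse$condition == cond &
                          timecourse$time_min == 0, ]
      if (!nrow(sub)) next
      h <- note(smoothHistogram(buildHistogram(
        geometricMeanDiameter(sub$diameter_long, sub$diameter_perp))))
      hists[[cond]] <- list(breaks = h@breaks, counts = h@counts,
                            degree = h@degree,
                            coefficients = h@coefficients, rss = h@rss)
    }
    if (length(hists)) res$histograms <- hists
  }
  res$warnings <- warningsSeen
  res
}

#' Analyse an ingested particle table
#'
#' Runs the tabulate / estimate / compare / summarize stages on records
#' that were ingested rather than simulated (visibility correction is
#' applied when a configuration supplying class geometries is given).
#'
#' @param records validated particle data.frame.
#' @param config optional [SimulationConfig-class] giving class diameters,
#'   protrusion length and multiplicity distributions for the correction.
#' @param control name of the reference condition (default "control").
#' @return list with \code{binding_tables}, \code{comparisons} and, when
#'   several time points are present, \code{diameter_summaries}.
#' @export
analyzeParticles <- function(records, config = NULL, control = "control") {
  validateParticles(records)
  tc <- if (length(unique(records$time_min)) > 1) records else NULL
  .analyze(binary = records, timecourse = tc, config = config,
           control = control)
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes simulate -> tabulate -> estimate -> compare -> summarize under
#' one seed, writing every table as delimited text, a provenance sidecar
#' (resolved configuration + seed + package version) and a single JSON
#' report. The report is byte-identically regenerable from the same
#' configuration and seed.
#'
#' @param config a [SimulationConfig-class]; alternatively give
#'   \code{configPath}.
#' @param configPath YAML configuration path (see
#'   [readSimulationConfig()]).
#' @param outDir output directory. Must not already contain files unless
#'   \code{force = TRUE}.
#' @param seed optional integer overriding the configured seed.
#' @param force overwrite an existing non-empty output directory.
#' @return the report, invisibly, as a nested list.
#' @examples
#' \donttest{
#' cfg <- simulationConfig(nParticles = 80, seed = 11)
#' rep <- runPipeline(cfg, outDir = file.path(tempdir(), "demo"),
#'                    force = TRUE)
#' names(rep)
#' }
#' @export
runPipeline <- function(config = NULL, configPath = NULL, outDir,
                        seed = NULL, force = FALSE) {
  if (is.null(config)) {
    if (is.null(configPath)) stop("give config or configPath", call. = FALSE)
    config <- readSimulationConfig(configPath)
  }
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) config@seed <- as.integer(seed)
  validObject(config)
  if (dir.exists(outDir) && length(list.files(outDir)) && !force)
    stop("output directory ", outDir,
         " is not empty; use force = TRUE to overwrite", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  message("stage simulate: seed ", config@seed)
  binary <- generatePopulation(config)
  ternary <- if (length(config@ternary))
    generateTernaryPopulation(config) else NULL
  timecourse <- if (length(config@timecourse))
    generateTimecourse(config) else NULL

  writeParticles(binary, file.path(outDir, "particles_binary.csv"))
  if (!is.null(ternary))
    writeParticles(ternary, file.path(outDir, "particles_ternary.csv"))
  if (!is.null(timecourse))
    writeParticles(timecourse, file.path(outDir, "particles_timecourse.csv"))

  message("stage analyze")
  res <- .analyze(binary = binary, ternary = ternary,
                  timecourse = timecourse, config = config)
  geomTable <- evaluateGeometry(.classGeometries(config))

  for (nm in c("binding_tables", "comparisons", "ternary_fractions",
               "diameter_summaries")) {
    if (!is.null(res[[nm]]))
      write.csv(res[[nm]], file.path(outDir, paste0(nm, ".csv")),
                row.names = FALSE)
  }
  write.csv(geomTable, file.path(outDir, "geometry_models.csv"),
            row.names = FALSE)

  report <- c(list(
    package = "lipobind",
    version = as.character(packageVersion("lipobind")),
    seed = config@seed,
    config = configAsList(config),
    geometry_models = geomTable), res)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  yaml::write_yaml(list(package = "lipobind",
                        version = as.character(packageVersion("lipobind")),
                        seed = config@seed,
                        config = configAsList(config)),
                   file.path(outDir, "provenance.yaml"))
  message("report written to ", file.path(outDir, "report.json"))
  invisible(report)
}
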