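#' Geometric-mean particle diameter
#'
#' Per-particle size is the geometric mean of the longest diameter and the
#' diameter perpendicular to it, \code{sqrt(long * perp)} — less sensitive
#' to mild projection ellipticity than either axis alone.
#'
#' @param diameterLong,diameterPerp the two perpendicular diameter
#'   measurements in nm, both > 0. Vectorised.
#' @return diameter in nm.
#' @examples
#' geometricMeanDiameter(9, 16)  # 12
#' @export
geometricMeanDiameter <- function(diameterLong, diameterPerp) {
  .checkPositive(diameterLong, "diameterLong", strict = TRUE)
  .checkPositive(diameterPerp, "diameterPerp", strict = TRUE)
  sqrt(diameterLong * diameterPerp)
}

#' Diameter histogram with fixed sampling step
#'
#' Bins are left-closed, right-open, of constant width (default 0.5 nm),
#' with the left edge anchored at \code{floor(min / binWidth) * binWidth}.
#' An optional polynomial smoothing curve can be attached with
#' [smoothHistogram()]; smoothing annotates the object and never mutates
#' the counts.
#'
#' @slot breaks numeric bin edges (nm), strictly increasing, constant step.
#' @slot counts integer counts per bin; \code{sum(counts) == n}.
#' @slot degree numeric; degree of the fitted smoothing polynomial
#'   (\code{NA} before smoothing).
#' @slot coefficients numeric polynomial coefficients (ascending powers of
#'   the bin midpoint), empty before smoothing.
#' @slot fitted numeric fitted curve values at bin midpoints.
#' @slot rss numeric residual sum of squares of the fit.
#' @export
setClass("DiameterHistogram",
  representation(breaks = "numeric", counts = "integer", degree = "numeric",
                 coefficients = "numeric", fitted = "numeric",
                 rss = "numeric"),
  prototype(degree = NA_real_, coefficients = numeric(0),
            fitted = numeric(0), rss = NA_real_)
)

setValidity("DiameterHistogram", function(object) {
  msg <- character(0)
  b <- object@breaks
  if (length(b) < 2L || is.unsorted(b, strictly = TRUE))
    msg <- c(msg, "breaks must be strictly increasing, length >= 2")
  w <- diff(b)
  if (length(w) && max(abs(w - w[1])) > 1e-9)
    msg <- c(msg, "breaks must have a constant step")
  if (length(object@counts) != length(b) - 1L)
    msg <- c(msg, "counts must have one entry per bin")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiameterHistogram", function(object) {
  cat(sprintf("DiameterHistogram: %d particles in %d bins of %.2g nm over [%.2f, %.2f) nm\n",
              sum(object@counts), length(object@counts),
              diff(object@breaks)[1], min(object@breaks),
              max(object@breaks)))
  if (!is.na(object@degree))
    cat(sprintf("  smoothed with a degree-%d polynomial (RSS = %.4g)\n",
                as.integer(object@degree), object@rss))
  invisible(object)
})

#' @rdname DiameterHistogram-class
#' @param x a \code{DiameterHistogram}.
#' @export
histogramBreaks <- function(x) x@breaks
#' @rdname DiameterHistogram-class
#' @export
histogramCounts <- function(x) x@counts
#' @rdname DiameterHistogram-class
#' @export
histogramMidpoints <- function(x) (x@breaks[-1] + x@breaks[-length(x@breaks)]) / 2
#' @rdname DiameterHistogram-class
#' @export
smoothingCoefficients <- function(x) x@coefficients

#' Build a fixed-step diameter histogram
#'
#' @param diameters numeric diameters in nm, all > 0, non-empty.
#' @param binWidth bin width in nm (default 0.5, the sampling step used for
#'   lipoprotein size distributions).
#' @return a [DiameterHistogram-class].
#' @examples
#' h <- buildHistogram(c(10.0, 10.49, 10.5))
#' histogramCounts(h)  # 2, 1
#' @export
buildHistogram <- function(diameters, binWidth = 0.5) {
  if (length(diameters) == 0L) stop("empty diameter set", call. = FALSE)
  .checkPositive(diameters, "diameters", strict = TRUE)
  .checkPositive(binWidth, "binWidth", strict = TRUE)
  lo <- floor(min(diameters) / binWidth) * binWidth
  nBins <- floor((max(diameters) - lo) / binWidth) + 1L
  breaks <- lo + binWidth * (0:nBins)
  # left-closed, right-open bins
  idx <- pmin(floor((diameters - lo) / binWidth) + 1L, nBins)
  counts <- tabulate(idx, nbins = nBins)
  new("DiameterHistogram", breaks = breaks, counts = as.integer(counts))
}

#' Fit a polynomial smoothing curve to a histogram
#'
#' Least-squares polynomial of the requested degree (default 6) fitted to
#' (bin midpoint, count). When fewer occupied bins than \code{degree + 1}
#' are available the degree is reduced to occupied bins - 1, with a
#' warning. Counts are never modified.
#'
#' @param hist a [DiameterHistogram-class].
#' @param degree polynomial degree (default 6).
#' @return the histogram with \code{degree}, \code{coefficients},
#'   \code{fitted} and \code{rss} slots filled.
#' @export
smoothHistogram <- function(hist, degree = 6L) {
  stopifnot(is(hist, "DiameterHistogram"))
  if (degree < 0) stop("degree must be >= 0", call. = FALSE)
  occupied <- sum(hist@counts > 0)
  if (occupied < degree + 1) {
    degree <- occupied - 1L
    warning("too few occupied bins; polynomial degree reduced to ", degree)
  }
  mids <- histogramMidpoints(hist)
  y <- as.numeric(hist@counts)
  fit <- if (degree == 0) lm(y ~ 1) else
    lm(y ~ poly(mids, degree = degree, raw = TRUE))
  hist@degree <- as.numeric(degree)
  hist@coefficients <- unname(coef(fit))
  hist@fitted <- unname(fitted(fit))
  hist@rss <- sum(residuals(fit)^2)
  hist
}

#' Per-group diameter summaries and time-course percent change
#'
#' Computes, for every group (default class x condition x time), the count,
#' arithmetic mean and sample SD (n - 1 denominator) of the per-particle
#' geometric-mean diameters, and the percent change of the group mean
#' relative to the time-0 group of the same class and condition.
#'
#' @param records validated particle data.frame.
#' @param by grouping columns (default class, condition, time_min).
#' @param percentChange compute percent change vs the time-0 group
#'   (requires \code{"time_min"} in \code{by}; errors when a group has no
#'   time-0 reference).
#' @return data.frame with columns \code{class}, \code{condition},
#'   \code{time_min}, \code{n}, \code{mean_diameter}, \code{sd_diameter},
#'   \code{percent_change_from_t0}.
#' @examples
#' cfg <- simulationConfig(nParticles = 200, seed = 6)
#' tc <- generateTimecourse(cfg, conditions = "control")
#' summarizeDiameters(tc)
#' @export
summarizeDiameters <- function(records,
                               by = c("class", "condition", "time_min"),
                               percentChange = "time_min" %in% by) {
  validateParticles(records)
  d <- geometricMeanDiameter(records$diameter_long, records$diameter_perp)
  keyDf <- records[, by, drop = FALSE]
  keys <- interaction(keyDf, drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(records)), keys)
  out <- do.call(rbind, lapply(pieces, function(ix) {
    row <- keyDf[ix[1], , drop = FALSE]
    row$n <- length(ix)
    row$mean_diameter <- mean(d[ix])
    row$sd_diameter <- if (length(ix) > 1) sd(d[ix]) else 0
    row
  }))
  rownames(out) <- NULL
  if (percentChange) {
    if (!"time_min" %in% by)
      stop("percent change requires time_min grouping", call. = FALSE)
    ref <- setdiff(by, "time_min")
    refKey <- if (length(ref))
      interaction(out[, ref, drop = FALSE], drop = FALSE, sep = "\r")
    else factor(rep(1, nrow(out)))
    out$percent_change_from_t0 <- NA_real_
    for (k in unique(refKey)) {
      ix <- which(refKey == k)
      t0 <- ix[out$time_min[ix] == 0]
      if (!length(t0))
        stop("no time-0 reference group for ",
             gsub("\r", "/", as.character(k)), call. = FALSE)
      m0 <- out$mean_diameter[t0[1]]
      out$percent_change_from_t0[ix] <-
        (out$mean_diameter[ix] - m0) / m0 * 100
    }
  }
  out[do.call(order, unname(as.list(out[, by, drop = FALSE]))), ,
      drop = FALSE]
}
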