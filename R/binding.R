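#' Per-condition binding counts for one lipoprotein class
#'
#' A particle is \emph{free} when no rod protrusion was observed,
#' \emph{ternary} when it is cross-referenced to a bridging partner, and
#' \emph{binary} otherwise. The multiplicity histogram maps observed
#' protrusion count (>= 1) to number of particles.
#'
#' @slot class,condition character(1) labels.
#' @slot nTotal,nFree,nBinary,nTernary integer counts;
#'   \code{nFree + nBinary + nTernary == nTotal}.
#' @slot multiplicity named integer vector (names = protrusion counts);
#'   sums to \code{nBinary + nTernary}.
#' @seealso [tabulateBinding()], [boundFraction()], [compareConditions()].
#' @export
setClass("BindingTable",
  representation(
    className = "character", condition = "character",
    nTotal = "integer", nFree = "integer",
    nBinary = "integer", nTernary = "integer",
    multiplicity = "integer"
  )
)

setValidity("BindingTable", function(object) {
  msg <- character(0)
  if (any(c(object@nTotal, object@nFree, object@nBinary, object@nTernary) < 0))
    msg <- c(msg, "counts must be non-negative")
  if (object@nFree + object@nBinary + object@nTernary != object@nTotal)
    msg <- c(msg, "nFree + nBinary + nTernary must equal nTotal")
  if (length(object@multiplicity) &&
      sum(object@multiplicity) != object@nBinary + object@nTernary)
    msg <- c(msg, "multiplicity histogram must sum to nBinary + nTernary")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BindingTable", function(object) {
  cat(sprintf("BindingTable %s / %s: %d particles (%d free, %d binary, %d ternary)\n",
              object@className, object@condition, object@nTotal, object@nFree,
              object@nBinary, object@nTernary))
  if (length(object@multiplicity)) {
    cat("  observed protrusions per bound particle:",
        paste(sprintf("%s:%d", names(object@multiplicity),
                      object@multiplicity), collapse = " "), "\n")
  }
  cat(sprintf("  bound fraction = %.4f\n", boundFraction(object)))
  invisible(object)
})

#' @rdname BindingTable-class
#' @param x a \code{BindingTable}.
#' @export
nTotal <- function(x) x@nTotal
#' @rdname BindingTable-class
#' @export
nFree <- function(x) x@nFree
#' @rdname BindingTable-class
#' @export
nBinary <- function(x) x@nBinary
#' @rdname BindingTable-class
#' @export
nTernary <- function(x) x@nTernary
#' @rdname BindingTable-class
#' @export
multiplicityHistogram <- function(x) x@multiplicity

#' Result of a two-condition chi-square comparison
#'
#' @slot statistic chi-square statistic (1 degree of freedom).
#' @slot df degrees of freedom.
#' @slot pValue p-value from the chi-square distribution (full precision;
#'   printed with a 2.2e-16 floor).
#' @slot yates logical; was Yates' continuity correction applied.
#' @slot significant logical; \code{pValue < 0.05}.
#' @seealso [compareConditions()].
#' @export
setClass("ComparisonResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric",
                 yates = "logical", significant = "logical")
)

setValidity("ComparisonResult", function(object) {
  msg <- character(0)
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must be in [0, 1]")
  if (object@significant != (object@pValue < 0.05))
    msg <- c(msg, "significant flag inconsistent with pValue < 0.05")
  if (length(msg)) msg else TRUE
})

#' @rdname ComparisonResult-class
#' @param p numeric p-value.
#' @return \code{formatPValue()} renders p for human-readable output,
#'   flooring values below 2.2e-16 at \code{"< 2.2e-16"}.
#' @export
formatPValue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", format(p, digits = 3))
}

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("Pearson chi-square%s: X-squared = %.4f, df = %d, p %s%s\n",
              if (object@yates) " (Yates corrected)" else "",
              object@statistic, as.integer(object@df),
              if (object@pValue < 2.2e-16) "" else "= ",
              formatPValue(object@pValue)))
  cat("  significant at alpha = 0.05:", object@significant, "\n")
  invisible(object)
})

#' @rdname ComparisonResult-class
#' @export
pValue <- function(x) x@pValue
#' @rdname ComparisonResult-class
#' @export
chiSquareStatistic <- function(x) x@statistic
#' @rdname ComparisonResult-class
#' @export
isSignificant <- function(x) x@significant

#' Tabulate particle records into binding tables
#'
#' Counts free / binary / ternary particles and the observed-protrusion
#' multiplicity histogram for every class x condition present in the
#' records.
#'
#' @param records validated particle data.frame (see [validateParticles()]).
#' @return named list of [BindingTable-class] objects, names
#'   \code{"<class>.<condition>"}.
#' @examples
#' cfg <- simulationConfig(nParticles = 100, seed = 5)
#' tabs <- tabulateBinding(generatePopulation(cfg, conditions = "control"))
#' tabs[["HDL.control"]]
#' @export
tabulateBinding <- function(records) {
  validateParticles(records)
  keys <- interaction(records$class, records$condition, drop = TRUE)
  out <- lapply(split(records, keys), function(grp) {
    tern <- !is.na(grp$ternary_partner) & grp$ternary_partner != ""
    free <- grp$observed_protrusions == 0 & !tern
    binary <- grp$observed_protrusions >= 1 & !tern
    bound <- grp$observed_protrusions[!free]
    mult <- if (length(bound)) {
      tb <- table(bound)
      setNames(as.integer(tb), names(tb))
    } else integer(0)
    new("BindingTable",
        className = grp$class[1], condition = grp$condition[1],
        nTotal = nrow(grp), nFree = sum(free),
        nBinary = sum(binary), nTernary = sum(tern),
        multiplicity = mult)
  })
  out[order(names(out))]
}

#' Observed bound fraction
#'
#' Fraction of particles with at least one observed protrusion (binary or
#' ternary), i.e. the raw percentage an annotator would report.
#'
#' @param table a [BindingTable-class].
#' @return fraction in [0, 1].
#' @export
boundFraction <- function(table) {
  stopifnot(is(table, "BindingTable"))
  if (table@nTotal == 0L) stop("empty binding table", call. = FALSE)
  (table@nBinary + table@nTernary) / table@nTotal
}

#' Probability that a bound particle shows at least one protrusion
#'
#' Under independent attachment orientations, a particle with true
#' multiplicity \code{k} is detected with probability
#' \code{1 - (1 - P)^k}; averaging over a multiplicity distribution gives
#' the per-bound-particle detection probability. With all mass on
#' \code{k = 1} this reduces to the single-protrusion visibility
#' probability.
#'
#' @param pVisible single-protrusion visibility probability in (0, 1].
#' @param multiplicity optional named probability vector over true
#'   multiplicities (as in [SimulationConfig-class]).
#' @return detection probability in (0, 1].
#' @export
detectionProbability <- function(pVisible, multiplicity = NULL) {
  if (pVisible <= 0 || pVisible > 1)
    stop("pVisible must be in (0, 1]", call. = FALSE)
  if (is.null(multiplicity)) return(pVisible)
  k <- as.numeric(names(multiplicity))
  sum(multiplicity * (1 - (1 - pVisible)^k))
}

#' Visibility-corrected bound fraction
#'
#' Scales the observed bound fraction by the inverse probability that a
#' bound particle shows at least one protrusion (computed from the
#' multiplicity distribution when given, else the single-protrusion
#' visibility probability from the geometry). Values that would exceed 1
#' are capped at 1 with a warning.
#'
#' @param table a [BindingTable-class].
#' @param geometry a [RodSphereGeometry-class] (sphere diameter = class mean
#'   diameter; rod length = protrusion length).
#' @param multiplicity optional true-multiplicity distribution.
#' @return corrected fraction in [0, 1].
#' @examples
#' # observed 10% binding on ~12.3 nm HDL with an 8 nm protrusion
#' g <- RodSphereGeometry(12.28, rodLength = 8)
#' @export
correctedBoundFraction <- function(table, geometry, multiplicity = NULL) {
  stopifnot(is(table, "BindingTable"), is(geometry, "RodSphereGeometry"))
  p1 <- visibilityProbability(geometry@sphereDiameter, geometry@rodLength)
  if (p1 <= 0)
    stop("visibility probability is 0; correction undefined", call. = FALSE)
  pDet <- detectionProbability(p1, multiplicity)
  corrected <- boundFraction(table) / pDet
  if (corrected > 1) {
    warning("corrected bound fraction exceeds 1; capped at 1.0")
    corrected <- 1
  }
  corrected
}

#' Ternary-complex fractions relative to each partner class
#'
#' Each ternary complex contributes one HDL and one LDL, so both tables
#' must report the same number of ternary complexes; the fractions are that
#' count divided by the total particles of each class (free + binary +
#' ternary).
#'
#' @param hdlTable,ldlTable [BindingTable-class] objects for the two
#'   partner classes.
#' @return named numeric: \code{hdl} and \code{ldl} ternary fractions.
#' @examples
#' # 12 bridges among 100 HDL and 60 LDL -> 0.12 and 0.20
#' @export
ternaryFractions <- function(hdlTable, ldlTable) {
  stopifnot(is(hdlTable, "BindingTable"), is(ldlTable, "BindingTable"))
  if (hdlTable@nTernary != ldlTable@nTernary)
    stop("inconsistent ternary counts: ", hdlTable@nTernary, " (HDL) vs ",
         ldlTable@nTernary, " (LDL)", call. = FALSE)
  if (hdlTable@nTotal == 0L || ldlTable@nTotal == 0L)
    stop("empty binding table", call. = FALSE)
  c(hdl = hdlTable@nTernary / hdlTable@nTotal,
    ldl = ldlTable@nTernary / ldlTable@nTotal)
}

#' Compare bound fractions of two conditions by Pearson chi-square
#'
#' Lays out the 2x2 bound/unbound x condition table and applies Pearson's
#' chi-square test with 1 degree of freedom; Yates' continuity correction
#' is on by default. Significance is judged at alpha = 0.05.
#'
#' @param tableA,tableB [BindingTable-class] objects.
#' @param yates apply the continuity correction (default TRUE).
#' @return a [ComparisonResult-class].
#' @examples
#' a <- new("BindingTable", class = "HDL", condition = "control",
#'          nTotal = 100L, nFree = 90L, nBinary = 10L, nTernary = 0L,
#'          multiplicity = c("1" = 10L))
#' b <- new("BindingTable", class = "HDL", condition = "drug",
#'          nTotal = 100L, nFree = 50L, nBinary = 50L, nTernary = 0L,
#'          multiplicity = c("1" = 50L))
#' compareConditions(a, b, yates = FALSE)
#' @export
compareConditions <- function(tableA, tableB, yates = TRUE) {
  stopifnot(is(tableA, "BindingTable"), is(tableB, "BindingTable"))
  boundA <- tableA@nBinary + tableA@nTernary
  boundB <- tableB@nBinary + tableB@nTernary
  m <- matrix(c(boundA, tableA@nFree, boundB, tableB@nFree),
              nrow = 2, byrow = TRUE,
              dimnames = list(condition = c(tableA@condition,
                                            tableB@condition),
                              status = c("bound", "free")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate 2x2 table (zero row or column total)", call. = FALSE)
  ht <- suppressWarnings(chisq.test(m, correct = yates))
  new("ComparisonResult",
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      pValue = unname(ht$p.value), yates = yates,
      significant = unname(ht$p.value) < 0.05)
}

#' @rdname BindingTable-class
#' @return \code{bindingTableAsData()} flattens a list of binding tables to
#'   one data.frame row per table (multiplicity histogram JSON-encoded).
#' @param tables named list of \code{BindingTable}s.
#' @export
bindingTableAsData <- function(tables) {
  do.call(rbind, lapply(unname(tables), function(tb) {
    data.frame(class = tb@className, condition = tb@condition,
               n_total = tb@nTotal, n_free = tb@nFree,
               n_binary = tb@nBinary, n_ternary = tb@nTernary,
               bound_fraction = boundFraction(tb),
               multiplicity = as.character(
                 jsonlite::toJSON(as.list(tb@multiplicity),
                                  auto_unbox = TRUE)),
               stringsAsFactors = FALSE)
  }))
}
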