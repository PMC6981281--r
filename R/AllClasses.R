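#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- model params

#' Parameters of the discrete-cycle cell-death model
#'
#' The model assumes active necrosis removes a constant fraction `r` of the
#' residual neuron population in every cycle of fixed length `periodDays`,
#' with detectable necrosis beginning at `onsetDays`. Residual neurons
#' entering cycle `k` are `n0 * (1 - r)^(k - 1)` and deaths during cycle `k`
#' are `n0 * r * (1 - r)^(k - 1)`.
#'
#' @slot n0 Initial neuron count per field (cells, > 0; real-valued, an
#'   expectation over 143 um x 143 um microscopy fields).
#' @slot r Per-cycle death ratio (dimensionless, `0 <= r < 1`).
#' @slot periodDays Cycle period in days (> 0).
#' @slot onsetDays Time at which detectable active necrosis begins (days,
#'   >= 0).
#'
#' @param n0,r,periodDays,onsetDays See slot descriptions. `onsetDays`
#'   defaults to `periodDays` (detection begins one period after death
#'   initiation).
#' @return `DeathModelParams()` returns a validated `DeathModelParams` object.
#' @examples
#' DeathModelParams(n0 = 30.3, r = 0.141, periodDays = 31, onsetDays = 31)
#' @aliases initialNeurons deathRatio periodDays onsetDays
#' @export DeathModelParams
#' @exportClass DeathModelParams
DeathModelParams <- setClass("DeathModelParams",
  slots = c(n0 = "numeric", r = "numeric",
            periodDays = "numeric", onsetDays = "numeric"))

setValidity("DeathModelParams", function(object) {
  msgs <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@n0) || object@n0 <= 0)
    msgs <- c(msgs, "'n0' must be a single finite value > 0")
  if (!sc(object@r) || object@r < 0 || object@r >= 1)
    msgs <- c(msgs, "'r' must satisfy 0 <= r < 1")
  if (!sc(object@periodDays) || object@periodDays <= 0)
    msgs <- c(msgs, "'periodDays' must be a single finite value > 0")
  if (!sc(object@onsetDays) || object@onsetDays < 0)
    msgs <- c(msgs, "'onsetDays' must be a single finite value >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DeathModelParams-class
#' @usage DeathModelParams(n0, r, periodDays, onsetDays = periodDays)
DeathModelParams <- function(n0, r, periodDays, onsetDays = periodDays) {
  new("DeathModelParams", n0 = as.numeric(n0), r = as.numeric(r),
      periodDays = as.numeric(periodDays), onsetDays = as.numeric(onsetDays))
}

#' @rdname DeathModelParams-class
setMethod("initialNeurons", "DeathModelParams", function(params) params@n0)
#' @rdname DeathModelParams-class
setMethod("deathRatio", "DeathModelParams", function(params) params@r)
#' @rdname DeathModelParams-class
setMethod("periodDays", "DeathModelParams", function(params) params@periodDays)
#' @rdname DeathModelParams-class
setMethod("onsetDays", "DeathModelParams", function(params) params@onsetDays)

setMethod("show", "DeathModelParams", function(object) {
  cat("DeathModelParams\n")
  cat(sprintf("  n0     : %.4g cells/field\n", object@n0))
  cat(sprintf("  r      : %.4g per cycle\n", object@r))
  cat(sprintf("  period : %.4g days\n", object@periodDays))
  cat(sprintf("  onset  : %.4g days\n", object@onsetDays))
})

#' Published fitted parameters for the 5xFAD occipital-cortex time course
#'
#' The reported optimum of the discrete-cycle model fitted to active-necrosis
#' counts in 5xFAD mouse occipital cortex: 30.3 initial neurons per
#' 143 um x 143 um field, per-cycle death ratio 0.141, cycle period 31 days,
#' detection onset 31 days. Under this set the model predicts 3.706 cells per
#' field at day 60.
#'
#' @return A [DeathModelParams-class] object.
#' @examples
#' activeNecrosisAt(fittedParams5xFAD(), 60)
#' @export
fittedParams5xFAD <- function() {
  DeathModelParams(n0 = 30.3, r = 0.141, periodDays = 31, onsetDays = 31)
}

# ------------------------------------------------------------------ time course

#' Per-field active-necrosis count time course
#'
#' Long-format observations: one row per (time point, microscopy field) with a
#' nonnegative integer count of active-necrosis events in that field.
#'
#' @slot records `data.frame` with columns `time_days` (numeric, >= 0),
#'   `field_id` (character) and `count` (nonnegative integer).
#' @slot fieldAreaUm Numeric length-2 field dimensions in micrometres
#'   (default `c(143, 143)`).
#'
#' @param records A `data.frame` with the three columns above.
#' @param fieldAreaUm Field dimensions in micrometres.
#' @return `NecrosisTimeCourse()` returns a validated object.
#' @export NecrosisTimeCourse
#' @exportClass NecrosisTimeCourse
NecrosisTimeCourse <- setClass("NecrosisTimeCourse",
  slots = c(records = "data.frame", fieldAreaUm = "numeric"))

setValidity("NecrosisTimeCourse", function(object) {
  msgs <- character()
  rec <- object@records
  need <- c("time_days", "field_id", "count")
  if (!all(need %in% names(rec)))
    return(paste0("'records' must have columns ",
                  paste(need, collapse = ", ")))
  if (nrow(rec) == 0L)
    msgs <- c(msgs, "'records' must contain at least one observation")
  if (!is.numeric(rec$time_days) || any(!is.finite(rec$time_days)) ||
      any(rec$time_days < 0))
    msgs <- c(msgs, "'time_days' must be finite and >= 0")
  if (!is.numeric(rec$count) || any(!is.finite(rec$count)) ||
      any(rec$count < 0) || any(rec$count != round(rec$count)))
    msgs <- c(msgs, "'count' must contain nonnegative integers")
  if (length(object@fieldAreaUm) != 2L || any(object@fieldAreaUm <= 0))
    msgs <- c(msgs, "'fieldAreaUm' must be two positive lengths (um)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname NecrosisTimeCourse-class
#' @usage NecrosisTimeCourse(records, fieldAreaUm = c(143, 143))
NecrosisTimeCourse <- function(records, fieldAreaUm = c(143, 143)) {
  records <- as.data.frame(records)
  records$field_id <- as.character(records$field_id)
  new("NecrosisTimeCourse", records = records,
      fieldAreaUm = as.numeric(fieldAreaUm))
}

#' @rdname NecrosisTimeCourse-class
#' @param x A `NecrosisTimeCourse`.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "NecrosisTimeCourse",
          function(x, ...) x@records)

setMethod("show", "NecrosisTimeCourse", function(object) {
  rec <- object@records
  tms <- sort(unique(rec$time_days))
  cat("NecrosisTimeCourse\n")
  cat(sprintf("  %d observations, %d time points (%s days)\n",
              nrow(rec), length(tms),
              paste(signif(tms, 4), collapse = ", ")))
  cat(sprintf("  field area: %g um x %g um\n",
              object@fieldAreaUm[1], object@fieldAreaUm[2]))
})

# --------------------------------------------------------------- parameter grid

#' Candidate grids for grid-search fitting
#'
#' Ordered candidate values for each parameter of the discrete-cycle model,
#' searched exhaustively by [fitModel()]. With `refine = TRUE` the coarse-grid
#' optimum is polished by coordinate-wise line search (within the grid hull)
#' until parameter changes fall below `tol`.
#'
#' @slot n0,r,periodDays,onsetDays Strictly increasing numeric candidate
#'   vectors, each within the parameter's domain.
#' @slot refine Logical; polish the grid optimum.
#' @slot tol Relative convergence tolerance of the refinement.
#'
#' @param n0,r,periodDays,onsetDays,refine,tol See slots.
#' @return `ParameterGrid()` returns a validated object.
#' @export ParameterGrid
#' @exportClass ParameterGrid
ParameterGrid <- setClass("ParameterGrid",
  slots = c(n0 = "numeric", r = "numeric", periodDays = "numeric",
            onsetDays = "numeric", refine = "logical", tol = "numeric"))

setValidity("ParameterGrid", function(object) {
  msgs <- character()
  chk <- function(x, nm, lo, hi, loOpen = FALSE) {
    if (length(x) == 0L || any(!is.finite(x)))
      return(sprintf("'%s' grid must be nonempty and finite", nm))
    if (is.unsorted(x, strictly = TRUE))
      return(sprintf("'%s' grid must be strictly increasing", nm))
    if ((loOpen && x[1] <= lo) || (!loOpen && x[1] < lo) || x[length(x)] > hi)
      return(sprintf("'%s' grid outside the parameter domain", nm))
    NULL
  }
  msgs <- c(msgs,
            chk(object@n0, "n0", 0, Inf, loOpen = TRUE),
            chk(object@r, "r", 0, 1 - 1e-12),
            chk(object@periodDays, "periodDays", 0, Inf, loOpen = TRUE),
            chk(object@onsetDays, "onsetDays", 0, Inf))
  if (length(object@refine) != 1L || is.na(object@refine))
    msgs <- c(msgs, "'refine' must be TRUE or FALSE")
  if (length(object@tol) != 1L || !is.finite(object@tol) || object@tol <= 0)
    msgs <- c(msgs, "'tol' must be a single positive value")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ParameterGrid-class
#' @usage ParameterGrid(n0, r, periodDays, onsetDays, refine = TRUE,
#'   tol = 1e-3)
ParameterGrid <- function(n0, r, periodDays, onsetDays, refine = TRUE,
                          tol = 1e-3) {
  new("ParameterGrid", n0 = as.numeric(n0), r = as.numeric(r),
      periodDays = as.numeric(periodDays), onsetDays = as.numeric(onsetDays),
      refine = refine, tol = tol)
}

#' Default fitting grid
#'
#' Covers n0 in \[5, 60\] cells (step 2.5), r in \[0.01, 0.6\] (step 0.01),
#' period in \[5, 90\] days (step 5) and onset in \[0, 90\] days (step 5),
#' about 4.7e5 combinations, with coordinate refinement enabled so the final
#' estimate is not limited to the coarse step sizes.
#'
#' @return A [ParameterGrid-class].
#' @export
defaultParameterGrid <- function() {
  ParameterGrid(n0 = seq(5, 60, by = 2.5),
                r = seq(0.01, 0.6, by = 0.01),
                periodDays = seq(5, 90, by = 5),
                onsetDays = seq(0, 90, by = 5),
                refine = TRUE, tol = 1e-3)
}

setMethod("show", "ParameterGrid", function(object) {
  cat("ParameterGrid\n")
  fmt <- function(x) sprintf("%d values in [%.4g, %.4g]",
                             length(x), x[1], x[length(x)])
  cat("  n0     :", fmt(object@n0), "\n")
  cat("  r      :", fmt(object@r), "\n")
  cat("  period :", fmt(object@periodDays), "days\n")
  cat("  onset  :", fmt(object@onsetDays), "days\n")
  cat(sprintf("  %s combinations; refine = %s (tol %.3g)\n",
              format(length(object@n0) * length(object@r) *
                     length(object@periodDays) * length(object@onsetDays),
                     big.mark = ","),
              object@refine, object@tol))
})

# ------------------------------------------------------------------- fit result

#' Result of a grid-search model fit
#'
#' @slot params Estimated [DeathModelParams-class].
#' @slot sse Objective value at the estimate (cells^2).
#' @slot nEvaluations Number of objective evaluations performed.
#' @slot fittedCurve `data.frame` (`time_days`, `observed_mean`, `fitted`)
#'   at the distinct observed times.
#' @slot degenerate `TRUE` when the data were all-zero counts, in which case
#'   the returned `r` sits at the grid's lower bound.
#' @slot onsetTied Whether the onset was constrained to equal the period.
#'
#' @aliases fittedParams fitSSE fittedCurve isDegenerate
#' @exportClass FitResult
setClass("FitResult",
  slots = c(params = "DeathModelParams", sse = "numeric",
            nEvaluations = "integer", fittedCurve = "data.frame",
            degenerate = "logical", onsetTied = "logical"))

setValidity("FitResult", function(object) {
  if (length(object@sse) != 1L || !is.finite(object@sse) || object@sse < 0)
    return("'sse' must be a single finite value >= 0")
  TRUE
})

#' @rdname FitResult-class
setMethod("fittedParams", "FitResult", function(fit) fit@params)
#' @rdname FitResult-class
setMethod("fitSSE", "FitResult", function(fit) fit@sse)
#' @rdname FitResult-class
setMethod("fittedCurve", "FitResult", function(fit) fit@fittedCurve)
#' @rdname FitResult-class
setMethod("isDegenerate", "FitResult", function(fit) fit@degenerate)

setMethod("show", "FitResult", function(object) {
  cat("FitResult",
      if (object@degenerate) "(degenerate: all-zero counts)" else "", "\n")
  p <- object@params
  cat(sprintf("  n0 = %.4g, r = %.4g, period = %.4g d, onset = %.4g d%s\n",
              p@n0, p@r, p@periodDays, p@onsetDays,
              if (object@onsetTied) " (onset tied to period)" else ""))
  cat(sprintf("  SSE = %.6g over %d time points (%d evaluations)\n",
              object@sse, nrow(object@fittedCurve), object@nEvaluations))
})

# ------------------------------------------------------------------- bootstrap

#' Percentile bootstrap intervals for fitted parameters
#'
#' @slot intervals `data.frame` with columns `parameter`, `lower`, `upper`.
#' @slot level Nominal coverage level.
#' @slot B Number of bootstrap replicates.
#' @slot seed Seed used for resampling.
#' @slot replicates `B x 4` matrix of refitted parameters
#'   (columns n0, r, periodDays, onsetDays).
#' @exportClass BootstrapInterval
setClass("BootstrapInterval",
  slots = c(intervals = "data.frame", level = "numeric", B = "integer",
            seed = "integer", replicates = "matrix"))

setValidity("BootstrapInterval", function(object) {
  iv <- object@intervals
  if (!all(c("parameter", "lower", "upper") %in% names(iv)))
    return("'intervals' must have columns parameter, lower, upper")
  if (any(iv$lower > iv$upper + 1e-12))
    return("interval lower bounds must not exceed upper bounds")
  if (object@level <= 0 || object@level >= 1)
    return("'level' must be in (0, 1)")
  TRUE
})

setMethod("show", "BootstrapInterval", function(object) {
  cat(sprintf("BootstrapInterval (%.0f%%, B = %d, seed = %d)\n",
              100 * object@level, object@B, object@seed))
  print(object@intervals, row.names = FALSE)
})

# ------------------------------------------------------------ biomarker dataset

#' Subject-level biomarker dataset
#'
#' One record per subject: a group label (e.g. nc / dc / MCI / AD) and a
#' positive concentration in pg/mL.
#'
#' @slot records `data.frame` with columns `subject_id`, `group`,
#'   `value_pg_ml` (> 0).
#' @param records A `data.frame` with the three columns above.
#' @return `BiomarkerDataset()` returns a validated object.
#' @export BiomarkerDataset
#' @exportClass BiomarkerDataset
BiomarkerDataset <- setClass("BiomarkerDataset",
  slots = c(records = "data.frame"))

setValidity("BiomarkerDataset", function(object) {
  rec <- object@records
  need <- c("subject_id", "group", "value_pg_ml")
  if (!all(need %in% names(rec)))
    return(paste0("'records' must have columns ",
                  paste(need, collapse = ", ")))
  if (nrow(rec) == 0L) return("'records' must be nonempty")
  if (!is.numeric(rec$value_pg_ml) || any(!is.finite(rec$value_pg_ml)) ||
      any(rec$value_pg_ml <= 0))
    return("'value_pg_ml' must be finite and > 0")
  TRUE
})

#' @rdname BiomarkerDataset-class
#' @usage BiomarkerDataset(records)
BiomarkerDataset <- function(records) {
  records <- as.data.frame(records)
  records$subject_id <- as.character(records$subject_id)
  records$group <- as.character(records$group)
  new("BiomarkerDataset", records = records)
}

#' @rdname BiomarkerDataset-class
#' @param x A `BiomarkerDataset`.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "BiomarkerDataset", function(x, ...) x@records)

setMethod("show", "BiomarkerDataset", function(object) {
  rec <- object@records
  tab <- table(rec$group)
  cat("BiomarkerDataset\n")
  cat(sprintf("  %d subjects in %d groups: %s\n", nrow(rec), length(tab),
              paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

# ----------------------------------------------------------------- group specs

#' Specification of one synthetic biomarker group
#'
#' Concentrations are generated log-normally: `exp(rnorm(n, logMean, logSd))`.
#'
#' @slot name Group label.
#' @slot n Number of subjects (>= 1).
#' @slot logMean Mean of log-concentration (log pg/mL).
#' @slot logSd Standard deviation of log-concentration (> 0).
#' @param name,n,logMean,logSd See slots.
#' @return `GroupSpec()` returns a validated object.
#' @export GroupSpec
#' @exportClass GroupSpec
GroupSpec <- setClass("GroupSpec",
  slots = c(name = "character", n = "integer",
            logMean = "numeric", logSd = "numeric"))

setValidity("GroupSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single nonempty label")
  if (object@n < 1L) return("'n' must be >= 1")
  if (!is.finite(object@logMean)) return("'logMean' must be finite")
  if (!is.finite(object@logSd) || object@logSd <= 0)
    return("'logSd' must be > 0")
  TRUE
})

#' @rdname GroupSpec-class
#' @usage GroupSpec(name, n, logMean, logSd)
GroupSpec <- function(name, n, logMean, logSd) {
  new("GroupSpec", name = as.character(name), n = as.integer(n),
      logMean = as.numeric(logMean), logSd = as.numeric(logSd))
}

#' Noise model for synthetic count generation
#'
#' @slot family `"poisson"` or `"negative_binomial"`. The negative binomial
#'   uses variance `mean + mean^2 / dispersion`.
#' @slot dispersion Overdispersion parameter (> 0; ignored for Poisson).
#' @param family,dispersion See slots.
#' @return `NoiseSpec()` returns a validated object.
#' @export NoiseSpec
#' @exportClass NoiseSpec
NoiseSpec <- setClass("NoiseSpec",
  slots = c(family = "character", dispersion = "numeric"))

setValidity("NoiseSpec", function(object) {
  if (!object@family %in% c("poisson", "negative_binomial"))
    return("'family' must be 'poisson' or 'negative_binomial'")
  if (object@family == "negative_binomial" &&
      (!is.finite(object@dispersion) || object@dispersion <= 0))
    return("'dispersion' must be > 0 for the negative binomial")
  TRUE
})

#' @rdname NoiseSpec-class
#' @usage NoiseSpec(family = "poisson", dispersion = NA_real_)
NoiseSpec <- function(family = "poisson", dispersion = NA_real_) {
  new("NoiseSpec", family = family, dispersion = as.numeric(dispersion))
}

# -------------------------------------------------------------------- ROC curve

#' Empirical ROC curve with area under the curve
#'
#' Operating points run from (0, 0) to (1, 1) with nondecreasing false- and
#' true-positive rates; ties in the score produce diagonal segments. The
#' stored `auc` is the trapezoidal area, identical to the pairwise
#' concordance probability (ties counted half).
#'
#' @slot points `data.frame` with columns `fpr`, `tpr`.
#' @slot auc Area under the curve in \[0, 1\].
#' @aliases rocAUC operatingPoints
#' @exportClass RocCurve
setClass("RocCurve", slots = c(points = "data.frame", auc = "numeric"))

setValidity("RocCurve", function(object) {
  pt <- object@points
  if (!all(c("fpr", "tpr") %in% names(pt)))
    return("'points' must have columns fpr, tpr")
  if (any(pt$fpr < -1e-12) || any(pt$fpr > 1 + 1e-12) ||
      any(pt$tpr < -1e-12) || any(pt$tpr > 1 + 1e-12))
    return("rates must lie in [0, 1]")
  if (is.unsorted(pt$fpr) || is.unsorted(pt$tpr))
    return("rates must be nondecreasing along the curve")
  if (object@auc < 0 || object@auc > 1)
    return("'auc' must lie in [0, 1]")
  TRUE
})

#' @rdname RocCurve-class
setMethod("rocAUC", "RocCurve", function(roc) roc@auc)
#' @rdname RocCurve-class
setMethod("operatingPoints", "RocCurve", function(roc) roc@points)

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d operating points, AUC = %.4f\n",
              nrow(object@points), object@auc))
})

# ------------------------------------------------------------------ test result

#' Rank-sum test result
#'
#' @slot statistic The Mann-Whitney U statistic for the first sample.
#' @slot pRaw Two-sided p-value.
#' @slot pAdjusted Bonferroni-adjusted p-value (`min(1, m * pRaw)`).
#' @slot nComparisons Number of comparisons `m` used for the adjustment.
#' @slot method `"exact"` (enumeration) or `"normal"` (tie-corrected normal
#'   approximation with continuity correction).
#' @exportClass RankSumResult
setClass("RankSumResult",
  slots = c(statistic = "numeric", pRaw = "numeric", pAdjusted = "numeric",
            nComparisons = "integer", method = "character"))

setValidity("RankSumResult", function(object) {
  if (object@pRaw < 0 || object@pRaw > 1)
    return("'pRaw' must lie in [0, 1]")
  if (object@pAdjusted < object@pRaw - 1e-12 || object@pAdjusted > 1 + 1e-12)
    return("'pAdjusted' must lie in [pRaw, 1]")
  TRUE
})

setMethod("show", "RankSumResult", function(object) {
  cat(sprintf("RankSumResult: U = %g, p = %.4g (%s), adjusted p = %.4g (m = %d)\n",
              object@statistic, object@pRaw, object@method,
              object@pAdjusted, object@nComparisons))
})

# ------------------------------------------------------------------ box summary

#' Five-number box-plot summary
#'
#' Median and quartiles by linear interpolation of order statistics; whiskers
#' at the most extreme observations within 1.5 interquartile ranges of the
#' quartiles.
#'
#' @slot median,q1,q3,whiskerLow,whiskerHigh Summary values in the data's
#'   units, satisfying `whiskerLow <= q1 <= median <= q3 <= whiskerHigh`.
#' @exportClass BoxSummary
setClass("BoxSummary",
  slots = c(median = "numeric", q1 = "numeric", q3 = "numeric",
            whiskerLow = "numeric", whiskerHigh = "numeric"))

setValidity("BoxSummary", function(object) {
  v <- c(object@whiskerLow, object@q1, object@median, object@q3,
         object@whiskerHigh)
  if (any(!is.finite(v))) return("all summaries must be finite")
  if (is.unsorted(v)) return("summaries must be ordered whiskerLow <= Q1 <= median <= Q3 <= whiskerHigh")
  TRUE
})

setMethod("show", "BoxSummary", function(object) {
  cat(sprintf("BoxSummary: whiskers [%g, %g], quartiles [%g, %g], median %g\n",
              object@whiskerLow, object@whiskerHigh,
              object@q1, object@q3, object@median))
})
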