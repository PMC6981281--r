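#' @include AllGenerics.R
NULL

#' Residual neurons entering a cell-death cycle
#'
#' Number of neurons still alive at the start of cycle `k`, under the
#' discrete-cycle model in which a constant fraction `r` of the residual
#' population dies in every cycle: `n0 * (1 - r)^(k - 1)`.
#'
#' @param params A [DeathModelParams-class] object.
#' @param k Cycle index (numeric, possibly fractional), `k >= 1`.
#' @return Expected neurons per field (numeric, same length as `k`).
#' @seealso [deathsInCycle()], [cyclesAtTime()]
#' @examples
#' p <- DeathModelParams(n0 = 100, r = 0.5, periodDays = 31)
#' residualNeurons(p, k = 3) # 25
#' @export
setGeneric("residualNeurons", function(params, k)
  standardGeneric("residualNeurons"))

#' Neurons dying during a cell-death cycle
#'
#' Expected deaths during cycle `k`: `n0 * r * (1 - r)^(k - 1)`, i.e. the
#' residual population entering cycle `k` times the per-cycle death ratio.
#' Equals `residualNeurons(params, k) - residualNeurons(params, k + 1)`.
#'
#' @inheritParams residualNeurons
#' @return Expected deaths per field during cycle `k` (numeric).
#' @examples
#' p <- DeathModelParams(n0 = 100, r = 0.5, periodDays = 31)
#' deathsInCycle(p, k = 1) # 50
#' @export
setGeneric("deathsInCycle", function(params, k)
  standardGeneric("deathsInCycle"))

#' Map calendar time to a fractional cycle index
#'
#' For `t >= onsetDays` returns the continuous cycle index
#' `k = (t - onsetDays) / periodDays + 1`; before onset returns `NA`
#' (the before-onset sentinel).
#'
#' @param params A [DeathModelParams-class] object.
#' @param tDays Time in days (numeric vector, all `>= 0`).
#' @return Fractional cycle index, `NA` before onset.
#' @export
setGeneric("cyclesAtTime", function(params, tDays)
  standardGeneric("cyclesAtTime"))

#' Expected active-necrosis count at a calendar time
#'
#' Composition of the deaths-per-cycle expression with the time-to-cycle map:
#' zero strictly before onset, `deathsInCycle(params, cyclesAtTime(params, t))`
#' from onset on. This is the model curve fitted to per-field counts.
#'
#' @inheritParams cyclesAtTime
#' @return Expected active-necrosis events per field (numeric).
#' @examples
#' p <- DeathModelParams(n0 = 30.3, r = 0.141, periodDays = 31, onsetDays = 31)
#' activeNecrosisAt(p, 60) # 3.706
#' @export
setGeneric("activeNecrosisAt", function(params, tDays)
  standardGeneric("activeNecrosisAt"))

#' Evaluate the model curve over an ordered time grid
#'
#' @param params A [DeathModelParams-class] object.
#' @param times Nondecreasing numeric vector of days, all `>= 0`.
#' @return A `data.frame` with columns `time_days` and `expected_cells`.
#' @export
setGeneric("simulateTrajectory", function(params, times)
  standardGeneric("simulateTrajectory"))

#' Sum-of-squares objective between model and observed mean counts
#'
#' Sum over distinct observed time points of the squared difference between
#' the per-time-point mean count and the model curve. Optionally weighted by
#' the number of fields at each time point.
#'
#' @param params A [DeathModelParams-class] object.
#' @param tc A [NecrosisTimeCourse-class] with at least two distinct times.
#' @param weighted Weight each time point by its number of fields
#'   (default `FALSE`).
#' @return The objective value (cells^2).
#' @export
setGeneric("sseObjective", function(params, tc, weighted = FALSE)
  standardGeneric("sseObjective"))

#' Fit the discrete-cycle death model by deterministic grid search
#'
#' Exhaustively evaluates [sseObjective()] over the Cartesian product of the
#' candidate grids, breaking exact ties by the lexicographically smallest
#' `(r, period, onset, n0)`, then (optionally) polishes the optimum by
#' coordinate-wise line search within the grid hull.
#'
#' @param tc A [NecrosisTimeCourse-class].
#' @param grid A [ParameterGrid-class] (default [defaultParameterGrid()]).
#' @param onsetTied Constrain the onset to equal the period (`FALSE` by
#'   default, in which case onset is a free parameter on its own grid).
#' @param weighted Passed to [sseObjective()].
#' @return A [FitResult-class].
#' @export
setGeneric("fitModel", function(tc, grid = defaultParameterGrid(),
                                onsetTied = FALSE, weighted = FALSE)
  standardGeneric("fitModel"))

#' Predict expected active necrosis at a time point from a fit
#'
#' @param fit A [FitResult-class].
#' @param tDays Time in days (numeric, `>= 0`).
#' @return Expected active-necrosis events per field.
#' @export
setGeneric("predictAt", function(fit, tDays) standardGeneric("predictAt"))

#' Percentile bootstrap confidence intervals for fitted parameters
#'
#' Resamples field records with replacement within each time point, refits on
#' each resample, and returns per-parameter percentile intervals.
#' Bit-reproducible for a fixed seed.
#'
#' @param tc A [NecrosisTimeCourse-class].
#' @param grid A [ParameterGrid-class].
#' @param B Number of bootstrap replicates (`>= 1`).
#' @param level Interval coverage level in (0, 1), default 0.95.
#' @param seed Integer seed.
#' @param onsetTied,weighted Passed to [fitModel()].
#' @return A [BootstrapInterval-class].
#' @export
setGeneric("bootstrapCI", function(tc, grid = defaultParameterGrid(), B = 200,
                                   level = 0.95, seed = 1, onsetTied = FALSE,
                                   weighted = FALSE)
  standardGeneric("bootstrapCI"))

#' @rdname DeathModelParams-class
#' @param params,object A `DeathModelParams` object.
#' @export
setGeneric("initialNeurons", function(params) standardGeneric("initialNeurons"))

#' @rdname DeathModelParams-class
#' @export
setGeneric("deathRatio", function(params) standardGeneric("deathRatio"))

#' @rdname DeathModelParams-class
#' @export
setGeneric("periodDays", function(params) standardGeneric("periodDays"))

#' @rdname DeathModelParams-class
#' @export
setGeneric("onsetDays", function(params) standardGeneric("onsetDays"))

#' @rdname FitResult-class
#' @param fit A `FitResult` object.
#' @export
setGeneric("fittedParams", function(fit) standardGeneric("fittedParams"))

#' @rdname FitResult-class
#' @export
setGeneric("fitSSE", function(fit) standardGeneric("fitSSE"))

#' @rdname FitResult-class
#' @export
setGeneric("fittedCurve", function(fit) standardGeneric("fittedCurve"))

#' @rdname FitResult-class
#' @export
setGeneric("isDegenerate", function(fit) standardGeneric("isDegenerate"))

#' @rdname RocCurve-class
#' @param roc A `RocCurve` object.
#' @export
setGeneric("rocAUC", function(roc) standardGeneric("rocAUC"))

#' @rdname RocCurve-class
#' @export
setGeneric("operatingPoints", function(roc) standardGeneric("operatingPoints"))
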