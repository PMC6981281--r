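#' @include AllClasses.R
NULL

# Grid-search least-squares estimation of the discrete-cycle model. The
# objective is the unweighted SSE between per-time-point mean counts and the
# model curve; the search is an exhaustive vectorised sweep of the Cartesian
# grid followed by coordinate-wise line search within the grid hull. Exact
# SSE ties are broken by the lexicographically smallest (r, period, onset,
# n0) so the fit is deterministic.

# model curve vectorised over parameter vectors at a single time point
.curveAtParams <- function(n0, r, p, onset, t) {
  v <- n0 * r * (1 - r)^((t - onset) / p)
  v[t < onset] <- 0
  v
}

.timeCourseMeans <- function(tc, forFit = TRUE) {
  rec <- tc@records
  tms <- sort(unique(rec$time_days))
  if (forFit && length(tms) < 2L)
    stop("fitting requires at least 2 distinct time points", call. = FALSE)
  means <- vapply(tms, function(t) mean(rec$count[rec$time_days == t]),
                  numeric(1))
  nfld <- vapply(tms, function(t) sum(rec$time_days == t), numeric(1))
  list(times = tms, means = means, nFields = nfld)
}

.sseVec <- function(n0, r, p, onset, obs, weights) {
  sse <- 0
  for (i in seq_along(obs$times)) {
    v <- .curveAtParams(n0, r, p, onset, obs$times[i])
    sse <- sse + weights[i] * (obs$means[i] - v)^2
  }
  sse
}

#' @rdname sseObjective
setMethod("sseObjective", signature(params = "DeathModelParams",
                                    tc = "NecrosisTimeCourse"),
  function(params, tc, weighted = FALSE) {
    obs <- .timeCourseMeans(tc)
    w <- if (weighted) obs$nFields else rep(1, length(obs$times))
    .sseVec(params@n0, params@r, params@periodDays, params@onsetDays, obs, w)
  })

# coordinate-wise line search around the grid optimum; steps start at the
# local grid spacing, the window re-centres while the optimum keeps moving
# ("walks"), and shrinks when a full cycle yields no improvement
.refineFit <- function(start, hull, obs, weights, tol, onsetTied) {
  cur <- start                              # c(n0, r, p, onset)
  evals <- 0L
  obj <- function(x) {
    evals <<- evals + 1L
    .sseVec(x[1], x[2], x[3], if (onsetTied) x[3] else x[4], obs, weights)
  }
  best <- obj(cur)
  w <- vapply(seq_len(4), function(j) {
    span <- hull[[j]][2] - hull[[j]][1]
    if (span <= 0) 0 else max(span / 20, tol)
  }, numeric(1))
  scale <- pmax(abs(cur), 1)
  active <- if (onsetTied) c(2L, 3L, 1L) else c(2L, 3L, 4L, 1L)
  for (cycle in seq_len(60L)) {
    improved <- FALSE
    for (j in active) {
      if (w[j] <= 0) next
      for (walk in seq_len(25L)) {
        lo <- max(hull[[j]][1], cur[j] - w[j])
        hi <- min(hull[[j]][2], cur[j] + w[j])
        if (hi - lo < 1e-12) break
        o <- stats::optimize(function(v) {
          x <- cur; x[j] <- v; obj(x)
        }, c(lo, hi), tol = max(w[j] * 1e-3, 1e-9))
        if (o$objective < best - 1e-14) {
          cur[j] <- o$minimum
          best <- o$objective
          improved <- TRUE
          atEdge <- (o$minimum - lo < w[j] * 0.05 && lo > hull[[j]][1]) ||
                    (hi - o$minimum < w[j] * 0.05 && hi < hull[[j]][2])
          if (!atEdge) break
        } else break
      }
    }
    if (!improved) {
      w <- w / 2
      if (all(w < tol * scale)) break
    }
  }
  if (onsetTied) cur[4] <- cur[3]
  list(par = cur, sse = best, evals = evals)
}

#' @rdname fitModel
setMethod("fitModel", "NecrosisTimeCourse",
  function(tc, grid = defaultParameterGrid(), onsetTied = FALSE,
           weighted = FALSE) {
    stopifnot(is(grid, "ParameterGrid"))
    obs <- .timeCourseMeans(tc)
    weights <- if (weighted) obs$nFields else rep(1, length(obs$times))

    degenerate <- all(tc@records$count == 0)
    if (degenerate) {
      par <- DeathModelParams(n0 = grid@n0[1], r = grid@r[1],
                              periodDays = grid@periodDays[1],
                              onsetDays = if (onsetTied) grid@periodDays[1]
                                          else grid@onsetDays[1])
      sse <- .sseVec(par@n0, par@r, par@periodDays, par@onsetDays,
                     obs, weights)
      return(new("FitResult", params = par, sse = sse, nEvaluations = 1L,
                 fittedCurve = data.frame(
                   time_days = obs$times, observed_mean = obs$means,
                   fitted = activeNecrosisAt(par, obs$times)),
                 degenerate = TRUE, onsetTied = onsetTied))
    }

    onsetGrid <- if (onsetTied) NA_real_ else grid@onsetDays
    combos <- expand.grid(n0 = grid@n0, r = grid@r, p = grid@periodDays,
                          onset = onsetGrid, KEEP.OUT.ATTRS = FALSE)
    if (onsetTied) combos$onset <- combos$p
    sse <- .sseVec(combos$n0, combos$r, combos$p, combos$onset, obs, weights)
    nEval <- nrow(combos)

    minSSE <- min(sse)
    cand <- which(sse == minSSE)
    if (length(cand) > 1L) {
      o <- order(combos$r[cand], combos$p[cand], combos$onset[cand],
                 combos$n0[cand])
      cand <- cand[o[1]]
    }
    est <- c(combos$n0[cand], combos$r[cand], combos$p[cand],
             combos$onset[cand])
    best <- minSSE

    if (grid@refine) {
      hull <- list(range(grid@n0), range(grid@r), range(grid@periodDays),
                   if (onsetTied) range(grid@periodDays)
                   else range(grid@onsetDays))
      ref <- .refineFit(est, hull, obs, weights, grid@tol, onsetTied)
      if (ref$sse <= best) {           # refinement never increases the SSE
        est <- ref$par
        best <- ref$sse
      }
      nEval <- nEval + ref$evals
    }

    par <- DeathModelParams(n0 = est[1], r = est[2], periodDays = est[3],
                            onsetDays = est[4])
    new("FitResult", params = par, sse = best,
        nEvaluations = as.integer(nEval),
        fittedCurve = data.frame(time_days = obs$times,
                                 observed_mean = obs$means,
                                 fitted = activeNecrosisAt(par, obs$times)),
        degenerate = FALSE, onsetTied = onsetTied)
  })

#' @rdname predictAt
setMethod("predictAt", "FitResult", function(fit, tDays) {
  if (any(!is.finite(tDays)) || any(tDays < 0))
    stop("'tDays' must be finite and >= 0", call. = FALSE)
  activeNecrosisAt(fit@params, tDays)
})

#' Construct a FitResult directly from known parameters
#'
#' Convenience for prediction workflows where the parameters are given (e.g.
#' a published fit) rather than estimated: wraps the parameters together with
#' their objective value on an optional time course.
#'
#' @param params A [DeathModelParams-class].
#' @param tc Optional [NecrosisTimeCourse-class] used to evaluate the SSE and
#'   fitted curve; if `NULL` the SSE is 0 and the curve empty.
#' @return A [FitResult-class].
#' @examples
#' fit <- asFitResult(fittedParams5xFAD())
#' predictAt(fit, 60)
#' @export
asFitResult <- function(params, tc = NULL) {
  stopifnot(is(params, "DeathModelParams"))
  if (is.null(tc)) {
    curve <- data.frame(time_days = numeric(), observed_mean = numeric(),
                        fitted = numeric())
    sse <- 0
  } else {
    obs <- .timeCourseMeans(tc, forFit = FALSE)
    curve <- data.frame(time_days = obs$times, observed_mean = obs$means,
                        fitted = activeNecrosisAt(params, obs$times))
    sse <- sum((curve$observed_mean - curve$fitted)^2)
  }
  new("FitResult", params = params, sse = sse, nEvaluations = 0L,
      fittedCurve = curve, degenerate = FALSE, onsetTied = FALSE)
}

#' @rdname bootstrapCI
setMethod("bootstrapCI", "NecrosisTimeCourse",
  function(tc, grid = defaultParameterGrid(), B = 200, level = 0.95,
           seed = 1, onsetTied = FALSE, weighted = FALSE) {
    if (B < 1L) stop("'B' must be >= 1", call. = FALSE)
    if (level <= 0 || level >= 1)
      stop("'level' must be in (0, 1)", call. = FALSE)
    rec <- tc@records
    byTime <- split(seq_len(nrow(rec)), rec$time_days)
    reps <- withr::with_seed(seed, {
      t(vapply(seq_len(B), function(b) {
        idx <- unlist(lapply(byTime, function(ii)
          ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
        boot <- NecrosisTimeCourse(rec[idx, , drop = FALSE],
                                   fieldAreaUm = tc@fieldAreaUm)
        p <- fittedParams(fitModel(boot, grid, onsetTied = onsetTied,
                                   weighted = weighted))
        c(n0 = p@n0, r = p@r, periodDays = p@periodDays,
          onsetDays = p@onsetDays)
      }, numeric(4)))
    })
    alpha <- (1 - level) / 2
    qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE, type = 7)
    new("BootstrapInterval",
        intervals = data.frame(parameter = colnames(reps),
                               lower = qs[1, ], upper = qs[2, ],
                               row.names = NULL),
        level = level, B = as.integer(B), seed = as.integer(seed),
        replicates = reps)
  })
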