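#' @include AllClasses.R
NULL

# Closed-form evaluation of the discrete-cycle cell-death model. All methods
# accept fractional (continuous) cycle indices: the curve between integer
# cycles is the geometric decay evaluated at k = (t - onset)/period + 1, which
# makes the post-onset curve an exponential in calendar time.

.checkCycle <- function(k) {
  if (any(!is.na(k) & k < 1))
    stop("cycle index 'k' must be >= 1", call. = FALSE)
}

#' @rdname residualNeurons
setMethod("residualNeurons", "DeathModelParams", function(params, k) {
  .checkCycle(k)
  params@n0 * (1 - params@r)^(k - 1)
})

#' @rdname deathsInCycle
setMethod("deathsInCycle", "DeathModelParams", function(params, k) {
  .checkCycle(k)
  params@n0 * params@r * (1 - params@r)^(k - 1)
})

#' @rdname cyclesAtTime
setMethod("cyclesAtTime", "DeathModelParams", function(params, tDays) {
  if (any(!is.finite(tDays)) || any(tDays < 0))
    stop("'tDays' must be finite and >= 0", call. = FALSE)
  k <- (tDays - params@onsetDays) / params@periodDays + 1
  k[tDays < params@onsetDays] <- NA_real_
  k
})

#' @rdname activeNecrosisAt
setMethod("activeNecrosisAt", "DeathModelParams", function(params, tDays) {
  k <- cyclesAtTime(params, tDays)
  out <- numeric(length(tDays))
  inside <- !is.na(k)
  out[inside] <- deathsInCycle(params, k[inside])
  out
})

#' @rdname simulateTrajectory
setMethod("simulateTrajectory", "DeathModelParams", function(params, times) {
  if (length(times) == 0L)
    stop("'times' must be nonempty", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and >= 0", call. = FALSE)
  if (is.unsorted(times))
    stop("'times' must be nondecreasing", call. = FALSE)
  data.frame(time_days = as.numeric(times),
             expected_cells = activeNecrosisAt(params, times))
})
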