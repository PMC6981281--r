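#' @include AllClasses.R
NULL

# Seeded generators that emulate the statistical structure of the study's
# inputs: per-field necrosis counts around the model curve, log-normal
# biomarker cohorts, and correlated marker pairs. All are pure functions of
# (arguments, seed): RNG state is scoped with withr::with_seed.

#' Default observation times for synthetic necrosis time courses
#'
#' Five sampling ages spanning 1 to 18 months (31, 92, 184, 368, 552 days),
#' matching the sparse longitudinal design of the mouse microscopy counts.
#'
#' @return Numeric vector of days.
#' @export
defaultNecrosisTimes <- function() c(31, 92, 184, 368, 552)

#' Generate a synthetic active-necrosis count time course
#'
#' For each time point and field, draws a count whose mean is the model curve
#' [activeNecrosisAt()]. Counts in a 143 um x 143 um field are rare events,
#' so the default noise family is Poisson; a negative binomial is available
#' for overdispersed (e.g. mouse-to-mouse) variation.
#'
#' @param params A [DeathModelParams-class]; defaults to the published 5xFAD
#'   fit [fittedParams5xFAD()].
#' @param times Observation times in days (default [defaultNecrosisTimes()]).
#' @param nFields Fields per time point (default 30, the study's replicate
#'   count).
#' @param noise A [NoiseSpec-class] (default Poisson).
#' @param seed Integer seed.
#' @return A [NecrosisTimeCourse-class].
#' @examples
#' tc <- generateNecrosisCounts(seed = 1)
#' head(as.data.frame(tc))
#' @export
generateNecrosisCounts <- function(params = fittedParams5xFAD(),
                                   times = defaultNecrosisTimes(),
                                   nFields = 30,
                                   noise = NoiseSpec("poisson"),
                                   seed = 1) {
  stopifnot(is(params, "DeathModelParams"), is(noise, "NoiseSpec"))
  if (nFields < 1L) stop("'nFields' must be >= 1", call. = FALSE)
  mu <- activeNecrosisAt(params, times)
  counts <- withr::with_seed(seed, {
    unlist(lapply(mu, function(m) {
      if (noise@family == "poisson") stats::rpois(nFields, m)
      else stats::rnbinom(nFields, mu = m, size = noise@dispersion)
    }))
  })
  NecrosisTimeCourse(data.frame(
    time_days = rep(times, each = nFields),
    field_id = sprintf("t%g_f%03d", rep(times, each = nFields),
                       rep(seq_len(nFields), length(times))),
    count = counts))
}

#' Closed-form binormal AUC between two log-normal group specifications
#'
#' For groups whose log-concentrations are normal, the probability that a
#' random draw from `spec1` exceeds one from `spec0` is
#' `pnorm((logMean1 - logMean0) / sqrt(logSd0^2 + logSd1^2))`. Used to
#' calibrate the cohort generator against a target discrimination.
#'
#' @param spec0,spec1 [GroupSpec-class] objects (control, case).
#' @return The binormal AUC in (0, 1).
#' @examples
#' binormalAUC(GroupSpec("nc", 19, 6, 0.5), GroupSpec("MCI", 21, 6.77, 0.5))
#' @export
binormalAUC <- function(spec0, spec1) {
  stopifnot(is(spec0, "GroupSpec"), is(spec1, "GroupSpec"))
  stats::pnorm((spec1@logMean - spec0@logMean) /
               sqrt(spec0@logSd^2 + spec1@logSd^2))
}

#' Default four-group cohort specification
#'
#' Mirrors the reference CSF cohort structure: normal control (nc, n = 19),
#' disease control (dc, n = 11), MCI (n = 21) and AD (n = 56). Log-means are
#' calibrated through the binormal closed form so the population AUCs match
#' the reported discriminations (MCI vs nc 0.861, MCI vs dc 0.931, MCI vs AD
#' 0.809), with a common log-SD of 0.5 and an nc median near 400 pg/mL.
#'
#' @return A named list of [GroupSpec-class] objects.
#' @export
defaultCohortSpecs <- function() {
  sd <- 0.5
  ncMean <- log(400)
  mciMean <- ncMean + stats::qnorm(0.861) * sd * sqrt(2)
  dcMean <- mciMean - stats::qnorm(0.931) * sd * sqrt(2)
  adMean <- mciMean - stats::qnorm(0.809) * sd * sqrt(2)
  list(nc = GroupSpec("nc", 19, ncMean, sd),
       dc = GroupSpec("dc", 11, dcMean, sd),
       MCI = GroupSpec("MCI", 21, mciMean, sd),
       AD = GroupSpec("AD", 56, adMean, sd))
}

#' Generate a synthetic multi-group biomarker cohort
#'
#' Log-normal concentrations per group: `exp(rnorm(n, logMean, logSd))`.
#' Concentrations are strictly positive and right-skewed, as CSF protein
#' measurements are.
#'
#' @param specs List of [GroupSpec-class] objects with distinct names
#'   (default [defaultCohortSpecs()]).
#' @param seed Integer seed.
#' @return A [BiomarkerDataset-class].
#' @examples
#' ds <- generateBiomarkerGroups(seed = 1)
#' ds
#' @export
generateBiomarkerGroups <- function(specs = defaultCohortSpecs(), seed = 1) {
  if (length(specs) < 2L)
    stop("at least 2 group specs are required", call. = FALSE)
  stopifnot(all(vapply(specs, is, logical(1), "GroupSpec")))
  nms <- vapply(specs, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    stop("group names must be distinct", call. = FALSE)
  recs <- withr::with_seed(seed, {
    do.call(rbind, lapply(specs, function(s) {
      data.frame(subject_id = sprintf("%s_%04d", s@name, seq_len(s@n)),
                 group = s@name,
                 value_pg_ml = exp(stats::rnorm(s@n, s@logMean, s@logSd)))
    }))
  })
  rownames(recs) <- NULL
  BiomarkerDataset(recs)
}

#' Generate a bivariate-normal pair with a target Pearson correlation
#'
#' Standard-normal marginals with population correlation `rho`, built as
#' `y = rho * x + sqrt(1 - rho^2) * z`.
#'
#' @param n Number of pairs (>= 3).
#' @param rho Target correlation, strictly between -1 and 1.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `x` and `y`.
#' @examples
#' pr <- generateCorrelatedPair(100, rho = 0.7, seed = 1)
#' cor(pr$x, pr$y)
#' @export
generateCorrelatedPair <- function(n, rho, seed = 1) {
  if (n < 3L) stop("'n' must be >= 3", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("'rho' must satisfy -1 < rho < 1", call. = FALSE)
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    data.frame(x = x, y = rho * x + sqrt(1 - rho^2) * z)
  })
}
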