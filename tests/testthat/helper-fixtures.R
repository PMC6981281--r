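# shared builders for small in-code fixtures

publishedParams <- function() fittedParams5xFAD()

# a tiny noiseless time course whose counts are exactly on the model curve:
# n0 = 40, r = 0.5, p = 31, onset = 31 gives 20, 10, 5 at days 31, 62, 93
exactCountParams <- function() DeathModelParams(40, 0.5, 31, 31)

exactCountCourse <- function() {
  NecrosisTimeCourse(data.frame(time_days = c(31, 62, 93),
                                field_id = paste0("f", 1:3),
                                count = c(20L, 10L, 5L)))
}

smallGrid <- function(refine = FALSE) {
  ParameterGrid(n0 = c(20, 40, 60), r = c(0.25, 0.5, 0.75),
                periodDays = c(20, 31, 45), onsetDays = c(10, 31, 50),
                refine = refine)
}

randomParams <- function() {
  DeathModelParams(n0 = runif(1, 5, 80), r = runif(1, 0.01, 0.9),
                   periodDays = runif(1, 5, 90),
                   onsetDays = runif(1, 0, 90))
}

# exhaustive two-sided rank-sum p over all choose(n+m, n) group assignments
bruteForceRankSumP <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  rk <- rank(pooled)
  nm <- n * (N - n)
  uAll <- apply(utils::combn(N, n), 2,
                function(ix) sum(rk[ix]) - n * (n + 1) / 2)
  uObs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  lo <- min(uObs, nm - uObs)
  hi <- max(uObs, nm - uObs)
  mean(uAll <= lo | uAll >= hi)
}

# pairwise-concordance AUC by explicit double loop
bruteForceAUC <- function(cases, controls) {
  conc <- 0
  for (a in cases) for (b in controls)
    conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(cases) * length(controls))
}
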