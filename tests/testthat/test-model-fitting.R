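# grid-search least squares: objective, search, refinement, prediction,
# bootstrap

test_that("sseObjective matches hand arithmetic on per-time-point means", {
  p <- publishedParams()
  tc <- NecrosisTimeCourse(data.frame(time_days = c(31, 60),
                                      field_id = c("a", "b"),
                                      count = c(4L, 3L)))
  expect_equal(sseObjective(p, tc),
               (4 - 4.2723)^2 + (3 - activeNecrosisAt(p, 60))^2)
  expect_equal(sseObjective(p, tc), 0.5726, tolerance = 1e-3)
  # data exactly on the curve give zero
  expect_equal(sseObjective(exactCountParams(), exactCountCourse()), 0)
  one <- NecrosisTimeCourse(data.frame(time_days = 31, field_id = "a",
                                       count = 4L))
  expect_error(sseObjective(p, one), "2 distinct time points")
  expect_error(NecrosisTimeCourse(data.frame(time_days = numeric(),
                                             field_id = character(),
                                             count = integer())))
})

test_that("a noiseless trajectory at a grid point is recovered exactly", {
  fit <- fitModel(exactCountCourse(), smallGrid())
  p <- fittedParams(fit)
  expect_equal(initialNeurons(p), 40)
  expect_equal(deathRatio(p), 0.5)
  expect_equal(periodDays(p), 31)
  expect_equal(onsetDays(p), 31)
  expect_equal(fitSSE(fit), 0)
  expect_false(isDegenerate(fit))
})

test_that("grid search equals an independent brute-force sweep of the grid", {
  for (seed in c(5, 17)) {
    tc <- generateNecrosisCounts(seed = seed)
    g <- ParameterGrid(n0 = seq(10, 50, by = 10), r = seq(0.05, 0.45, by = 0.05),
                       periodDays = seq(10, 80, by = 10),
                       onsetDays = seq(0, 80, by = 20), refine = FALSE)
    fit <- fitModel(tc, g)
    obs <- aggregate(count ~ time_days, as.data.frame(tc), mean)
    best <- Inf
    bestPar <- NULL
    for (n0 in g@n0) for (r in g@r) for (p in g@periodDays)
      for (o in g@onsetDays) {
        pr <- DeathModelParams(n0, r, p, o)
        s <- sum((obs$count - activeNecrosisAt(pr, obs$time_days))^2)
        if (s < best) {
          best <- s
          bestPar <- c(n0, r, p, o)
        }
      }
    p <- fittedParams(fit)
    expect_equal(fitSSE(fit), best)
    expect_equal(c(initialNeurons(p), deathRatio(p), periodDays(p),
                   onsetDays(p)), bestPar)
  }
})

test_that("refinement never increases the objective and stays in the hull", {
  for (seed in 1:4) {
    tc <- generateNecrosisCounts(seed = seed)
    g <- ParameterGrid(n0 = seq(10, 50, by = 10), r = seq(0.05, 0.45, by = 0.1),
                       periodDays = seq(10, 80, by = 20),
                       onsetDays = seq(0, 80, by = 40), refine = FALSE)
    coarse <- fitModel(tc, g)
    gRef <- ParameterGrid(g@n0, g@r, g@periodDays, g@onsetDays,
                          refine = TRUE, tol = 1e-4)
    refined <- fitModel(tc, gRef)
    expect_lte(fitSSE(refined), fitSSE(coarse))
    p <- fittedParams(refined)
    expect_true(initialNeurons(p) >= min(g@n0) &&
                initialNeurons(p) <= max(g@n0))
    expect_true(deathRatio(p) >= min(g@r) && deathRatio(p) <= max(g@r))
    expect_true(periodDays(p) >= min(g@periodDays) &&
                periodDays(p) <= max(g@periodDays))
    expect_true(onsetDays(p) >= min(g@onsetDays) &&
                onsetDays(p) <= max(g@onsetDays))
  }
})

test_that("equal-SSE grid ties break to the smallest (r, period, onset, n0)", {
  # all-flat data cannot distinguish curves that agree at the observed times;
  # two exact-tie candidates are built by matching amplitude at one time
  tc <- NecrosisTimeCourse(data.frame(time_days = c(40, 40, 80, 80),
                                      field_id = c("a", "b", "c", "d"),
                                      count = c(0L, 0L, 0L, 0L)))
  # degenerate path takes over for all-zero data: documented behaviour
  fit <- fitModel(tc, smallGrid())
  expect_true(isDegenerate(fit))
  expect_equal(deathRatio(fittedParams(fit)), min(smallGrid()@r))

  # non-degenerate exact tie: (n0=40, r=0.5, p=31) and (n0=80/3, r=0.75,
  # p=62) share the same daily decay (ln 4 / 62 = ln 2 / 31) and the same
  # value 20 at t=31, so both interpolate counts 20, 10 exactly; the
  # lexicographic rule must pick the smaller r
  tc2 <- NecrosisTimeCourse(data.frame(time_days = c(31, 62),
                                       field_id = c("a", "b"),
                                       count = c(20L, 10L)))
  g2 <- ParameterGrid(n0 = c(80 / 3, 40), r = c(0.5, 0.75),
                      periodDays = c(31, 62), onsetDays = 31,
                      refine = FALSE)
  fit2 <- fitModel(tc2, g2)
  expect_equal(fitSSE(fit2), 0)
  expect_equal(deathRatio(fittedParams(fit2)), 0.5)
  expect_equal(periodDays(fittedParams(fit2)), 31)
  expect_equal(initialNeurons(fittedParams(fit2)), 40)
})

test_that("predictAt matches the closed form and the fitted curve", {
  fit <- asFitResult(publishedParams())
  expect_equal(predictAt(fit, 60), 3.706, tolerance = 0.001 / 3.706)
  expect_identical(predictAt(fit, 10), 0)
  expect_equal(predictAt(fit, 31), 30.3 * 0.141)
  expect_error(predictAt(fit, -1), "tDays")
  # consistency with the fitted_curve entries at observed times
  tc <- generateNecrosisCounts(seed = 2)
  fit2 <- fitModel(tc, smallGrid(refine = TRUE))
  crv <- fittedCurve(fit2)
  expect_equal(predictAt(fit2, crv$time_days), crv$fitted)
})

test_that("the fitted curve converges to the truth as fields grow", {
  # the identifiable functional of the model is the post-onset curve itself:
  # with 10x the fields per time point the fitted curve error shrinks
  g <- ParameterGrid(n0 = seq(10, 60, by = 5), r = seq(0.02, 0.4, by = 0.02),
                     periodDays = seq(10, 60, by = 10),
                     onsetDays = c(0, 15, 31), refine = TRUE, tol = 1e-3)
  truth <- activeNecrosisAt(publishedParams(), defaultNecrosisTimes())
  err <- function(nFields, seed) {
    tc <- generateNecrosisCounts(nFields = nFields, seed = seed)
    mean(abs(fittedCurve(fitModel(tc, g))$fitted - truth))
  }
  errSmall <- median(vapply(1:5, function(s) err(30, s), numeric(1)))
  errLarge <- median(vapply(1:5, function(s) err(300, 100 + s), numeric(1)))
  expect_lt(errLarge, errSmall)
})

test_that("bootstrap intervals are seeded, ordered and degenerate at B = 1", {
  tc <- generateNecrosisCounts(seed = 6)
  g <- ParameterGrid(n0 = seq(15, 55, by = 5), r = seq(0.05, 0.3, by = 0.01),
                     periodDays = 31, onsetDays = 31, refine = FALSE)
  ci1 <- bootstrapCI(tc, g, B = 25, seed = 99)
  ci2 <- bootstrapCI(tc, g, B = 25, seed = 99)
  expect_identical(ci1@intervals, ci2@intervals)
  expect_identical(ci1@replicates, ci2@replicates)
  ci3 <- bootstrapCI(tc, g, B = 25, seed = 100)
  expect_false(identical(ci1@intervals, ci3@intervals))
  expect_true(all(ci1@intervals$lower <= ci1@intervals$upper))
  one <- bootstrapCI(tc, g, B = 1, seed = 7)
  expect_equal(one@intervals$lower, one@intervals$upper)
  expect_error(bootstrapCI(tc, g, B = 0), "B")
  expect_error(bootstrapCI(tc, g, B = 10, level = 1.2), "level")
})
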