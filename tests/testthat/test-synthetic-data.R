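# seeded generators: count time courses, biomarker cohorts, correlated pairs

test_that("count generator is seeded, mean-calibrated and honours r = 0", {
  tc1 <- generateNecrosisCounts(seed = 42)
  tc2 <- generateNecrosisCounts(seed = 42)
  expect_identical(as.data.frame(tc1), as.data.frame(tc2))
  tc3 <- generateNecrosisCounts(seed = 43)
  expect_false(identical(as.data.frame(tc1), as.data.frame(tc3)))
  # r = 0 means no deaths, hence all-zero counts
  silent <- generateNecrosisCounts(DeathModelParams(30, 0, 31, 31), seed = 1)
  expect_true(all(as.data.frame(silent)$count == 0))
  # law of large numbers: the empirical mean approaches the model curve
  big <- generateNecrosisCounts(times = 92, nFields = 1e5, seed = 8)
  mu <- activeNecrosisAt(fittedParams5xFAD(), 92)
  expect_equal(mean(as.data.frame(big)$count), mu, tolerance = 0.01)
})

test_that("negative-binomial counts are overdispersed relative to Poisson", {
  p <- fittedParams5xFAD()
  nb <- generateNecrosisCounts(p, times = 92, nFields = 2e4,
                               noise = NoiseSpec("negative_binomial",
                                                 dispersion = 2),
                               seed = 5)
  x <- as.data.frame(nb)$count
  mu <- activeNecrosisAt(p, 92)
  # variance ~ mu + mu^2 / dispersion, well above the Poisson variance mu
  expect_gt(var(x), 1.5 * mu)
  expect_equal(var(x), mu + mu^2 / 2, tolerance = 0.1)
  expect_error(NoiseSpec("negative_binomial"), "dispersion")
  expect_error(NoiseSpec("gamma"), "family")
})

test_that("binormal AUC closed form has the right symmetry and scale", {
  a <- GroupSpec("a", 10, 6, 0.5)
  expect_equal(binormalAUC(a, GroupSpec("b", 10, 6, 0.5)), 0.5)
  shifted <- GroupSpec("b", 10, 6 + 0.5 * sqrt(2), 0.5)
  expect_equal(binormalAUC(a, shifted), pnorm(1))
  below <- GroupSpec("b", 10, 5.5, 0.5)
  expect_lt(binormalAUC(a, below), 0.5)
  expect_equal(binormalAUC(a, below), 1 - binormalAUC(below, a))
})

test_that("cohort generator hits its binormal AUC target and is seeded", {
  s0 <- GroupSpec("ctl", 1e5, 6, 0.5)
  s1 <- GroupSpec("case", 1e5, 6.5, 0.5)
  ds <- generateBiomarkerGroups(list(s0, s1), seed = 4)
  d <- as.data.frame(ds)
  expect_true(all(d$value_pg_ml > 0))
  emp <- aucStat(d$value_pg_ml, d$group == "case")
  expect_equal(emp, binormalAUC(s0, s1), tolerance = 0.005 / binormalAUC(s0, s1))
  ds2 <- generateBiomarkerGroups(list(s0, s1), seed = 4)
  expect_identical(as.data.frame(ds2), d)
  expect_error(generateBiomarkerGroups(list(s0), seed = 1), "at least 2")
  expect_error(generateBiomarkerGroups(list(s0, s0), seed = 1), "distinct")
})

test_that("default cohort mirrors the reference group sizes and AUCs", {
  specs <- defaultCohortSpecs()
  expect_equal(vapply(specs, function(s) s@n, integer(1)),
               c(nc = 19L, dc = 11L, MCI = 21L, AD = 56L))
  expect_equal(binormalAUC(specs$nc, specs$MCI), 0.861, tolerance = 1e-6)
  expect_equal(binormalAUC(specs$dc, specs$MCI), 0.931, tolerance = 1e-6)
  expect_equal(binormalAUC(specs$AD, specs$MCI), 0.809, tolerance = 1e-6)
  ds <- generateBiomarkerGroups(seed = 1)
  expect_equal(nrow(as.data.frame(ds)), 19 + 11 + 21 + 56)
})

test_that("correlated pairs reach the target rho and reject |rho| >= 1", {
  pr <- generateCorrelatedPair(1e5, 0.9, seed = 2)
  expect_equal(cor(pr$x, pr$y), 0.9, tolerance = 0.01 / 0.9)
  pr0 <- generateCorrelatedPair(1e5, 0, seed = 3)
  expect_lt(abs(cor(pr0$x, pr0$y)), 0.01)
  pr1 <- generateCorrelatedPair(50, 0.5, seed = 9)
  expect_identical(generateCorrelatedPair(50, 0.5, seed = 9), pr1)
  expect_error(generateCorrelatedPair(100, 1), "rho")
  expect_error(generateCorrelatedPair(2, 0.5), "n")
})
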