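# from-scratch discrimination toolkit vs independent oracles

test_that("rank-sum exact p equals brute-force enumeration, ties included", {
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))@pRaw, 0.1)
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))@statistic, 0)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- sample(1:8, n, replace = TRUE) # heavy ties
    y <- sample(1:8, m, replace = TRUE)
    expect_equal(rankSumTest(x, y, method = "exact")@pRaw,
                 bruteForceRankSumP(x, y))
  }
  # identical multisets sit exactly at the null centre
  x <- c(2, 4, 4, 7)
  ts <- rankSumTest(x, x)
  expect_equal(ts@statistic, length(x)^2 / 2)
  expect_gt(ts@pRaw, 0.9)
})

test_that("rank-sum agrees with wilcox.test in both regimes", {
  x <- c(1.1, 3.2, 5.5, 7.1)
  y <- c(2.0, 4.4, 6.6, 8.8, 9.9)
  expect_equal(rankSumTest(x, y, method = "exact")@pRaw,
               wilcox.test(x, y, exact = TRUE)$p.value)
  set.seed(7)
  x2 <- rpois(40, 5)
  y2 <- rpois(50, 6)
  expect_equal(rankSumTest(x2, y2, method = "normal")@pRaw,
               wilcox.test(x2, y2, exact = FALSE, correct = TRUE)$p.value)
  # strongly shifted large samples are overwhelmingly significant
  set.seed(8)
  a <- rnorm(100)
  b <- rnorm(100, mean = 2)
  expect_lt(rankSumTest(a, b)@pRaw, 1e-6)
  expect_error(rankSumTest(numeric(), 1:3), "nonempty")
})

test_that("normal approximation tracks the exact p for n, m >= 8", {
  set.seed(12)
  for (i in 1:15) {
    # untied samples: the approximation sits within 0.02 of the exact p
    x <- rnorm(sample(8:14, 1))
    y <- rnorm(sample(8:14, 1), 0.5)
    pe <- rankSumTest(x, y, method = "exact")@pRaw
    pn <- rankSumTest(x, y, method = "normal")@pRaw
    expect_lt(abs(pe - pn), 0.02)
    # heavily tied small samples can deviate a little more; the tie-corrected
    # approximation is still the standard one (identical to wilcox.test)
    xt <- rpois(sample(8:14, 1), 5)
    yt <- rpois(sample(8:14, 1), 6)
    expect_lt(abs(rankSumTest(xt, yt, method = "exact")@pRaw -
                  rankSumTest(xt, yt, method = "normal")@pRaw), 0.05)
  }
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroniAdjust(0.01, m = 3), 0.03)
  expect_equal(bonferroniAdjust(0.5, m = 4), 1)
  expect_equal(bonferroniAdjust(0, m = 10), 0)
  expect_equal(bonferroniAdjust(c(0.01, 0.02), m = 2),
               p.adjust(c(0.01, 0.02), "bonferroni"))
  expect_error(bonferroniAdjust(1.2), "0, 1")
  expect_error(bonferroniAdjust(c(0.1, 0.2), m = 1), "at least")
})

test_that("AUC equals the pairwise concordance count, ties counted half", {
  expect_equal(aucStat(c(3, 5, 7, 1, 2, 6), c(1, 1, 1, 0, 0, 0)), 7 / 9)
  expect_equal(aucStat(c(2, 2), c(1, 0)), 0.5)
  expect_equal(aucStat(c(10, 11, 12, 1, 2, 3), rep(c(1, 0), each = 3)), 1)
  set.seed(21)
  for (i in 1:40) {
    nc <- sample(2:12, 1)
    nk <- sample(2:12, 1)
    cases <- sample(1:6, nc, replace = TRUE)
    controls <- sample(1:6, nk, replace = TRUE)
    expect_equal(aucStat(c(cases, controls),
                         rep(c(TRUE, FALSE), c(nc, nk))),
                 bruteForceAUC(cases, controls))
  }
})

test_that("AUC-U duality holds exactly: auc = U / (n * m)", {
  set.seed(33)
  for (i in 1:40) {
    n <- sample(3:15, 1)
    m <- sample(3:15, 1)
    v <- sample(1:7, n + m, replace = TRUE)
    lab <- rep(c(TRUE, FALSE), c(n, m))
    U <- rankSumTest(v[lab], v[!lab])@statistic
    expect_equal(aucStat(v, lab), U / (n * m))
  }
})

test_that("ROC curves are monotone, anchored, and integrate to the AUC", {
  v <- c(3, 5, 7, 1, 2, 6)
  l <- c(1, 1, 1, 0, 0, 0)
  roc <- rocPoints(v, l)
  pts <- operatingPoints(roc)
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ], use.names = FALSE), c(1, 1))
  expect_equal(rocAUC(roc), aucStat(v, l))
  # perfectly separated classes pass through (0, 1)
  sep <- rocPoints(c(10, 11, 1, 2), c(1, 1, 0, 0))
  expect_true(any(sep@points$fpr == 0 & sep@points$tpr == 1))
  expect_equal(rocAUC(sep), 1)
  # random labels at large n sit near chance, and the trapezoidal area
  # equals the pairwise statistic to machine precision across random draws
  set.seed(14)
  for (i in 1:25) {
    vv <- rnorm(60)
    ll <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
    if (all(ll) || !any(ll)) next
    expect_equal(rocAUC(rocPoints(vv, ll)), aucStat(vv, ll),
                 tolerance = 1e-12)
  }
  vbig <- rnorm(4000)
  lbig <- rep(c(TRUE, FALSE), 2000)
  expect_equal(aucStat(vbig, lbig), 0.5, tolerance = 0.05)
  expect_error(rocPoints(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC and ROC match pROC on tied integer scores", {
  skip_if_not_installed("pROC")
  set.seed(50)
  v <- rpois(80, 4)
  l <- rep(c(1, 0), 40)
  ours <- aucStat(v, l)
  theirs <- as.numeric(pROC::auc(pROC::roc(l, v, direction = "<",
                                           quiet = TRUE)))
  expect_equal(ours, theirs)
})

test_that("Pearson correlation matches cor() and is affine-invariant", {
  expect_equal(pearsonR(1:4, c(2, 4, 5, 9)), cor(1:4, c(2, 4, 5, 9)))
  expect_equal(pearsonR(1:4, c(2, 4, 5, 9)), 0.96476, tolerance = 1e-4)
  x <- c(1, 5, 2, 8, 3)
  expect_equal(pearsonR(x, x), 1)
  expect_equal(pearsonR(x, -x), -1)
  set.seed(61)
  for (i in 1:20) {
    a <- rnorm(15)
    b <- rnorm(15)
    expect_equal(pearsonR(a, b), cor(a, b))
    expect_equal(pearsonR(2.5 * a + 7, b), pearsonR(a, b))
    expect_equal(pearsonR(a, 0.1 * b - 3), pearsonR(a, b))
  }
  tst <- pearsonRTest(rnorm(10), rnorm(10))
  expect_true(tst$p.value >= 0 && tst$p.value <= 1)
  a2 <- rnorm(12)
  b2 <- rnorm(12)
  expect_equal(pearsonRTest(a2, b2)$p.value, cor.test(a2, b2)$p.value)
  expect_error(pearsonR(c(1, 1, 1), 1:3), "constant")
  expect_error(pearsonR(1:2, 1:2), "3 pairs")
})

test_that("box summaries follow the 1.5 IQR whisker rule", {
  b <- boxSummary(c(1, 2, 3, 4, 5))
  expect_equal(c(b@q1, b@median, b@q3), c(2, 3, 4))
  expect_equal(c(b@whiskerLow, b@whiskerHigh), c(1, 5))
  out <- boxSummary(c(1, 2, 3, 4, 100))
  expect_equal(out@whiskerHigh, 4) # 100 is beyond Q3 + 1.5 IQR
  expect_equal(out@whiskerLow, 1)
  konst <- boxSummary(rep(7, 10))
  expect_equal(c(konst@whiskerLow, konst@q1, konst@median, konst@q3,
                 konst@whiskerHigh), rep(7, 5))
  # quartiles use the linear-interpolation convention
  set.seed(77)
  x <- rnorm(43)
  bb <- boxSummary(x)
  expect_equal(c(bb@q1, bb@median, bb@q3),
               unname(quantile(x, c(0.25, 0.5, 0.75), type = 7)))
  expect_error(boxSummary(numeric()), "nonempty")
})
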