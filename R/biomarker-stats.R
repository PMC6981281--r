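#' @include AllClasses.R
NULL

# From-scratch group-discrimination toolkit: Wilcoxon rank-sum (exact by
# dynamic-programming enumeration of rank assignments, or tie-corrected
# normal approximation with continuity correction), Bonferroni adjustment,
# empirical ROC/AUC and Pearson correlation. Tied observations receive
# midranks throughout, so the AUC-U duality auc = U/(n*m) holds exactly.

# exact permutation distribution of the rank sum via subset-sum counting:
# midranks are doubled to integers; dp[j+1, s+1] = number of j-subsets of the
# pooled ranks with doubled-rank sum s. Counting subsets is equivalent to
# enumerating all choose(n+m, n) group assignments.
.exactRankSumTail <- function(ranksAll, n, uObs) {
  s <- as.integer(round(2 * ranksAll))
  N <- length(s)
  maxS <- sum(sort(s, decreasing = TRUE)[seq_len(n)])
  dp <- matrix(0, nrow = n + 1L, ncol = maxS + 1L)
  dp[1L, 1L] <- 1
  for (v in s) {
    jmax <- min(n, N)
    for (j in seq(jmax, 1L)) {
      src <- seq_len(maxS + 1L - v)
      dp[j + 1L, src + v] <- dp[j + 1L, src + v] + dp[j, src]
    }
  }
  counts <- dp[n + 1L, ]
  total <- sum(counts)
  # doubled U values for each doubled rank sum s: 2U = s - n(n+1)
  u2 <- seq(0L, maxS) - n * (n + 1L)
  m <- N - n
  nm2 <- 2L * n * m
  uObs2 <- round(2 * uObs)
  lo <- min(uObs2, nm2 - uObs2)
  hi <- max(uObs2, nm2 - uObs2)
  min(1, sum(counts[u2 <= lo | u2 >= hi]) / total)
}

#' Wilcoxon rank-sum test with midranks
#'
#' Two-sided two-sample rank-sum test. For small problems
#' (`length(x) * length(y) <= 400`, the default `"auto"` switch) the p-value
#' is computed by exact enumeration of all rank assignments (handling ties);
#' otherwise by the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction.
#'
#' @param x,y Nonempty numeric samples.
#' @param comparisons Number of comparisons for the Bonferroni adjustment
#'   carried in the result (default 1 = no adjustment).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return A [RankSumResult-class]; the statistic is the Mann-Whitney U for
#'   `x` (0 <= U <= n*m).
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
rankSumTest <- function(x, y, comparisons = 1L,
                        method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("samples must be finite", call. = FALSE)
  n <- as.numeric(length(x))
  m <- as.numeric(length(y))
  pooled <- c(x, y)
  rk <- rank(pooled)                      # midranks for ties
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  if (method == "auto") method <- if (n * m <= 400) "exact" else "normal"
  if (method == "exact") {
    p <- .exactRankSumTail(rk, n, U)
  } else {
    N <- n + m
    ties <- table(pooled)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1                              # all observations tied
    } else {
      z <- (U - n * m / 2)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  new("RankSumResult", statistic = U, pRaw = p,
      pAdjusted = min(1, comparisons * p),
      nComparisons = as.integer(comparisons), method = method)
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of comparisons `m` and clipped
#' at 1.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param m Number of comparisons, at least `length(pvals)`.
#' @return Adjusted p-values.
#' @examples
#' bonferroniAdjust(c(0.01, 0.5), m = 3)
#' @export
bonferroniAdjust <- function(pvals, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(pvals))
    stop("'m' must be at least the number of p-values", call. = FALSE)
  pmin(1, m * pvals)
}

.splitByLabel <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length", call. = FALSE)
  lab <- as.logical(labels)
  if (any(is.na(lab)))
    stop("'labels' must be coercible to logical (TRUE = case)",
         call. = FALSE)
  if (!any(lab) || all(lab))
    stop("both classes must be present", call. = FALSE)
  list(cases = values[lab], controls = values[!lab])
}

#' Pairwise-concordance AUC
#'
#' The probability that a random case scores above a random control, with
#' ties counted half: `(#\{case > control\} + 0.5 * #\{case = control\}) /
#' (n_case * n_control)`. Computed via midranks, which is exactly the
#' pairwise count. Cases are the higher-score class by convention; values
#' below 0.5 are reported as-is.
#'
#' @param values Numeric scores.
#' @param labels Case/control labels coercible to logical (`TRUE` = case).
#' @return The AUC in \[0, 1\].
#' @examples
#' aucStat(c(3, 5, 7, 1, 2, 6), c(1, 1, 1, 0, 0, 0)) # 7/9
#' @export
aucStat <- function(values, labels) {
  cls <- .splitByLabel(values, labels)
  n <- as.numeric(length(cls$cases))
  m <- as.numeric(length(cls$controls))
  rk <- rank(c(cls$cases, cls$controls))
  (sum(rk[seq_len(n)]) - n * (n + 1) / 2) / (n * m)
}

#' Empirical ROC curve
#'
#' Operating points over all distinct score thresholds (case = higher score),
#' always anchored at (0, 0) and (1, 1); tied scores across classes produce
#' diagonal segments. The trapezoidal area equals [aucStat()] exactly.
#'
#' @inheritParams aucStat
#' @return A [RocCurve-class].
#' @examples
#' roc <- rocPoints(c(3, 5, 7, 1, 2, 6), c(1, 1, 1, 0, 0, 0))
#' rocAUC(roc)
#' @export
rocPoints <- function(values, labels) {
  cls <- .splitByLabel(values, labels)
  n <- length(cls$cases)
  m <- length(cls$controls)
  thr <- sort(unique(values), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(cls$cases >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(cls$controls >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fp / m), tpr = c(0, tp / n))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                               utils::tail(pts$tpr, -1)) / 2)
  new("RocCurve", points = pts, auc = area)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @examples
#' pearsonR(1:4, c(2, 4, 5, 9))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 pairs are required", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("inputs must be finite", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx2 <- sum(dx^2)
  sy2 <- sum(dy^2)
  if (sx2 == 0 || sy2 == 0)
    stop("correlation is undefined for constant input", call. = FALSE)
  sum(dx * dy) / sqrt(sx2 * sy2)
}

#' Pearson correlation with a two-sided p-value
#'
#' The t-transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @inheritParams pearsonR
#' @return A list with `estimate`, `statistic`, `df` and `p.value`.
#' @export
pearsonRTest <- function(x, y) {
  r <- pearsonR(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(estimate = r, statistic = tstat, df = n - 2L,
       p.value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Box-plot summary
#'
#' Median and quartiles by linear interpolation between order statistics
#' (`quantile()` type 7); whiskers at the most extreme observations within
#' 1.5 interquartile ranges beyond the quartiles.
#'
#' @param values Nonempty numeric sample.
#' @return A [BoxSummary-class].
#' @examples
#' boxSummary(c(1, 2, 3, 4, 100)) # upper whisker at 4
#' @export
boxSummary <- function(values) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be nonempty and finite", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  iqr <- q[3] - q[1]
  inLow <- values[values >= q[1] - 1.5 * iqr]
  inHigh <- values[values <= q[3] + 1.5 * iqr]
  new("BoxSummary", median = q[2], q1 = q[1], q3 = q[3],
      whiskerLow = min(inLow), whiskerHigh = max(inHigh))
}
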