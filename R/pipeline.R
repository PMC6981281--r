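#' @include AllClasses.R
NULL

# Config-driven orchestration of the analysis stages: simulate -> fit ->
# predict for count time courses, and cohort-generate -> compare -> ROC for
# biomarker tables. Configs are flat key-value lists (optionally read from a
# YAML file); every run writes a manifest echoing the fully resolved
# configuration and seed, so outputs are reproducible byte-for-byte from the
# manifest alone.

.defaultConfigs <- function() {
  list(
    simulate = list(
      task = "simulate", out_dir = ".", seed = 1L,
      n0 = 30.3, r = 0.141, period_days = 31, onset_days = 31,
      times = defaultNecrosisTimes(), n_fields = 30L,
      noise_family = "poisson", dispersion = NA_real_, quiet = FALSE),
    fit = list(
      task = "fit", input = NULL, out_dir = ".", seed = 1L,
      grid_n0_min = 5, grid_n0_max = 60, grid_n0_step = 2.5,
      grid_r_min = 0.01, grid_r_max = 0.6, grid_r_step = 0.01,
      grid_period_min = 5, grid_period_max = 90, grid_period_step = 5,
      grid_onset_min = 0, grid_onset_max = 90, grid_onset_step = 5,
      refine = TRUE, tol = 1e-3, onset_tied = FALSE, weighted = FALSE,
      bootstrap_B = 0L, bootstrap_level = 0.95, quiet = FALSE),
    predict = list(
      task = "predict", out_dir = ".", seed = 1L,
      n0 = NA_real_, r = NA_real_, period_days = NA_real_,
      onset_days = NA_real_, fit_report = NULL,
      times = defaultNecrosisTimes(), quiet = FALSE),
    biomarker = list(
      task = "biomarker", input = NULL, out_dir = ".", seed = 1L,
      contrasts = NULL, rank_sum_method = "auto", quiet = FALSE))
}

#' Default pipeline configuration for a task
#'
#' @param task One of `"simulate"`, `"fit"`, `"predict"`, `"biomarker"`.
#' @return A named list of configuration defaults.
#' @examples
#' defaultConfig("fit")$grid_r_step
#' @export
defaultConfig <- function(task = c("simulate", "fit", "predict",
                                   "biomarker")) {
  task <- match.arg(task)
  .defaultConfigs()[[task]]
}

#' Print a task's default configuration as YAML
#'
#' @inheritParams defaultConfig
#' @return The YAML string, invisibly.
#' @export
showConfig <- function(task = c("simulate", "fit", "predict", "biomarker")) {
  txt <- yaml::as.yaml(defaultConfig(task))
  cat(txt)
  invisible(txt)
}

# merge a user config (list or YAML path) over the task defaults
.resolveConfig <- function(config, task) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML path",
                             call. = FALSE)
  base <- defaultConfig(task)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  base[names(config)] <- config
  base$task <- task
  base
}

.writeManifest <- function(cfg, outputs, dir) {
  .writeJSON(list(package = "necrokinetics",
                  version = as.character(utils::packageVersion("necrokinetics")),
                  seed = cfg$seed, config = cfg, outputs = outputs),
             file.path(dir, "manifest.json"))
}

.ensureDir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Generate a synthetic count time course and write it to disk
#'
#' @param config A flat configuration list or YAML path; see
#'   `defaultConfig("simulate")` for the keys.
#' @return Invisibly, the paths of the written files.
#' @export
runSimulate <- function(config = list()) {
  cfg <- .resolveConfig(config, "simulate")
  dir <- .ensureDir(cfg$out_dir)
  .logmsg("simulate: generating counts (seed ", cfg$seed, ")",
          quiet = cfg$quiet)
  params <- DeathModelParams(cfg$n0, cfg$r, cfg$period_days, cfg$onset_days)
  tc <- generateNecrosisCounts(params, times = as.numeric(cfg$times),
                               nFields = cfg$n_fields,
                               noise = NoiseSpec(cfg$noise_family,
                                                 cfg$dispersion),
                               seed = cfg$seed)
  countsPath <- file.path(dir, "counts.csv")
  writeTimeCourse(tc, countsPath)
  .writeManifest(cfg, list(counts = "counts.csv"), dir)
  .logmsg("simulate: wrote ", countsPath, quiet = cfg$quiet)
  invisible(c(counts = countsPath,
              manifest = file.path(dir, "manifest.json")))
}

.gridFromConfig <- function(cfg) {
  ParameterGrid(
    n0 = seq(cfg$grid_n0_min, cfg$grid_n0_max, by = cfg$grid_n0_step),
    r = seq(cfg$grid_r_min, cfg$grid_r_max, by = cfg$grid_r_step),
    periodDays = seq(cfg$grid_period_min, cfg$grid_period_max,
                     by = cfg$grid_period_step),
    onsetDays = seq(cfg$grid_onset_min, cfg$grid_onset_max,
                    by = cfg$grid_onset_step),
    refine = cfg$refine, tol = cfg$tol)
}

#' Fit the death model to a count table and write a JSON report
#'
#' Reads the long-format count table named by `config$input`, runs the
#' grid-search fit (optionally with bootstrap intervals when
#' `bootstrap_B > 0`), and writes `fit.json`, `fitted_curve.csv` and a
#' manifest to `config$out_dir`.
#'
#' @param config A flat configuration list or YAML path; see
#'   `defaultConfig("fit")`.
#' @return Invisibly, the [FitResult-class] (with written file paths in
#'   attribute `"paths"`).
#' @export
runFit <- function(config = list()) {
  cfg <- .resolveConfig(config, "fit")
  if (is.null(cfg$input)) stop("'input' count table is required",
                               call. = FALSE)
  tc <- readTimeCourse(cfg$input)
  dir <- .ensureDir(cfg$out_dir)
  grid <- .gridFromConfig(cfg)
  .logmsg("fit: grid search over ",
          length(grid@n0) * length(grid@r) * length(grid@periodDays) *
            (if (cfg$onset_tied) 1L else length(grid@onsetDays)),
          " combinations", quiet = cfg$quiet)
  fit <- fitModel(tc, grid, onsetTied = cfg$onset_tied,
                  weighted = cfg$weighted)
  ci <- NULL
  if (cfg$bootstrap_B > 0L) {
    .logmsg("fit: bootstrap with B = ", cfg$bootstrap_B,
            quiet = cfg$quiet)
    ci <- bootstrapCI(tc, grid, B = cfg$bootstrap_B,
                      level = cfg$bootstrap_level, seed = cfg$seed,
                      onsetTied = cfg$onset_tied, weighted = cfg$weighted)
  }
  writeFitReport(fit, file.path(dir, "fit.json"), ci = ci)
  utils::write.table(fit@fittedCurve, file.path(dir, "fitted_curve.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  .writeManifest(cfg, list(fit = "fit.json",
                           fitted_curve = "fitted_curve.csv"), dir)
  .logmsg("fit: done, SSE = ", signif(fit@sse, 6), quiet = cfg$quiet)
  attr(fit, "paths") <- c(fit = file.path(dir, "fit.json"),
                          fitted_curve = file.path(dir, "fitted_curve.csv"),
                          manifest = file.path(dir, "manifest.json"))
  invisible(fit)
}

#' Predict expected counts at chosen times and write them to disk
#'
#' Parameters come either from the flat keys (`n0`, `r`, `period_days`,
#' `onset_days`) or from a previously written `fit.json` via `fit_report`.
#'
#' @param config A flat configuration list or YAML path; see
#'   `defaultConfig("predict")`.
#' @return Invisibly, the predictions `data.frame`.
#' @export
runPredict <- function(config = list()) {
  cfg <- .resolveConfig(config, "predict")
  if (!is.null(cfg$fit_report)) {
    rep <- jsonlite::read_json(cfg$fit_report, simplifyVector = TRUE)
    params <- DeathModelParams(rep$parameters$n0, rep$parameters$r,
                               rep$parameters$period_days,
                               rep$parameters$onset_days)
  } else {
    if (any(is.na(c(cfg$n0, cfg$r, cfg$period_days, cfg$onset_days))))
      stop("either 'fit_report' or all of n0/r/period_days/onset_days ",
           "must be given", call. = FALSE)
    params <- DeathModelParams(cfg$n0, cfg$r, cfg$period_days,
                               cfg$onset_days)
  }
  dir <- .ensureDir(cfg$out_dir)
  pred <- simulateTrajectory(params, sort(as.numeric(cfg$times)))
  utils::write.table(pred, file.path(dir, "predictions.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  .writeManifest(cfg, list(predictions = "predictions.csv"), dir)
  .logmsg("predict: wrote ", file.path(dir, "predictions.csv"),
          quiet = cfg$quiet)
  invisible(pred)
}

# parse "case|ctrlA,ctrlB" contrast strings
.parseContrast <- function(s, groups) {
  halves <- strsplit(s, "|", fixed = TRUE)[[1]]
  if (length(halves) != 2L)
    stop(sprintf("contrast '%s' must have the form 'case|control[,control]'",
                 s), call. = FALSE)
  case <- trimws(halves[1])
  controls <- trimws(strsplit(halves[2], ",", fixed = TRUE)[[1]])
  unknown <- setdiff(c(case, controls), groups)
  if (length(unknown))
    stop(sprintf("contrast '%s' names unknown group(s): %s", s,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  list(case = case, controls = controls,
       label = paste0(case, "_vs_", paste(controls, collapse = "-")))
}

#' Compare biomarker groups and write discrimination reports
#'
#' Runs all pairwise rank-sum tests with Bonferroni correction over the
#' number of pairs, computes a box summary per group, and an ROC curve for
#' each configured contrast (`"case|control"` or `"case|ctrlA,ctrlB"`, cases
#' being the higher-score class). With no configured contrasts, all ordered
#' pairs in order of first appearance are used (later group = case).
#'
#' @param config A flat configuration list or YAML path; see
#'   `defaultConfig("biomarker")`.
#' @return Invisibly, a list with the test table, box summaries and ROC
#'   curves.
#' @export
runBiomarker <- function(config = list()) {
  cfg <- .resolveConfig(config, "biomarker")
  if (is.null(cfg$input)) stop("'input' biomarker table is required",
                               call. = FALSE)
  ds <- readBiomarkerTable(cfg$input)
  rec <- ds@records
  groups <- unique(rec$group)
  if (length(groups) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  dir <- .ensureDir(cfg$out_dir)

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  m <- length(pairs)
  .logmsg("biomarker: ", m, " pairwise comparisons among ",
          length(groups), " groups", quiet = cfg$quiet)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    x <- rec$value_pg_ml[rec$group == pr[1]]
    y <- rec$value_pg_ml[rec$group == pr[2]]
    ts <- rankSumTest(x, y, comparisons = m, method = cfg$rank_sum_method)
    data.frame(group1 = pr[1], group2 = pr[2], U = ts@statistic,
               p_raw = ts@pRaw, p_adjusted = ts@pAdjusted,
               n_comparisons = ts@nComparisons, method = ts@method)
  }))

  boxes <- do.call(rbind, lapply(groups, function(g) {
    b <- boxSummary(rec$value_pg_ml[rec$group == g])
    data.frame(group = g, whisker_low = b@whiskerLow, q1 = b@q1,
               median = b@median, q3 = b@q3, whisker_high = b@whiskerHigh)
  }))

  contrasts <- cfg$contrasts
  if (is.null(contrasts))
    contrasts <- unlist(lapply(utils::combn(seq_along(groups), 2,
                                            simplify = FALSE),
                               function(ij) paste0(groups[ij[2]], "|",
                                                   groups[ij[1]])))
  rocs <- list()
  rocFiles <- character()
  for (s in contrasts) {
    ct <- .parseContrast(s, groups)
    keep <- rec$group %in% c(ct$case, ct$controls)
    roc <- rocPoints(rec$value_pg_ml[keep],
                     rec$group[keep] == ct$case)
    rocs[[ct$label]] <- roc
    f <- paste0("roc_", ct$label, ".csv")
    utils::write.table(cbind(roc@points,
                             auc = rep(roc@auc, nrow(roc@points))),
                       file.path(dir, f), sep = ",", row.names = FALSE,
                       quote = FALSE)
    rocFiles <- c(rocFiles, f)
  }

  utils::write.table(tests, file.path(dir, "tests.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(boxes, file.path(dir, "box_summaries.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  .writeJSON(list(groups = as.list(table(rec$group)),
                  n_comparisons = m,
                  auc = lapply(rocs, function(r) r@auc)),
             file.path(dir, "report.json"))
  .writeManifest(cfg, list(tests = "tests.csv",
                           box_summaries = "box_summaries.csv",
                           roc = as.list(rocFiles),
                           report = "report.json"), dir)
  .logmsg("biomarker: done", quiet = cfg$quiet)
  invisible(list(tests = tests, boxSummaries = boxes, rocCurves = rocs))
}
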