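#' @include AllClasses.R
NULL

# Delimited-text readers/writers for the two table schemas. Delimiters are
# auto-detected among comma and tab; schema violations raise errors naming
# the offending column or data row.

#' Read an active-necrosis count table
#'
#' Long format, one row per (time point, field): columns `time_days`,
#' `field_id`, `count`. Comma or tab delimited (auto-detected).
#'
#' @param path Path to the delimited file.
#' @param fieldAreaUm Field dimensions in micrometres.
#' @return A [NecrosisTimeCourse-class].
#' @export
readTimeCourse <- function(path, fieldAreaUm = c(143, 143)) {
  delim <- .detectDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  need <- c("time_days", "field_id", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$count) | df$count < 0 |
               df$count != round(df$count))
  if (length(bad))
    stop(sprintf("'%s': non-integer or negative count at data row %d", path,
                 bad[1]), call. = FALSE)
  bad <- which(!is.finite(df$time_days) | df$time_days < 0)
  if (length(bad))
    stop(sprintf("'%s': invalid time_days at data row %d", path, bad[1]),
         call. = FALSE)
  NecrosisTimeCourse(df[need], fieldAreaUm = fieldAreaUm)
}

#' Write an active-necrosis count table
#'
#' @param tc A [NecrosisTimeCourse-class].
#' @param path Output path (`.tsv` extension writes tab-delimited, otherwise
#'   comma).
#' @return `path`, invisibly.
#' @export
writeTimeCourse <- function(tc, path) {
  stopifnot(is(tc, "NecrosisTimeCourse"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(tc@records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a subject-level biomarker table
#'
#' Columns `subject_id`, `group`, `value_pg_ml`; comma or tab delimited.
#'
#' @param path Path to the delimited file.
#' @return A [BiomarkerDataset-class].
#' @export
readBiomarkerTable <- function(path) {
  delim <- .detectDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "value_pg_ml")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$value_pg_ml) | df$value_pg_ml <= 0)
  if (length(bad))
    stop(sprintf("'%s': nonpositive concentration at data row %d", path,
                 bad[1]), call. = FALSE)
  BiomarkerDataset(df[need])
}

#' Write a subject-level biomarker table
#'
#' @param ds A [BiomarkerDataset-class].
#' @param path Output path (`.tsv` writes tab-delimited, otherwise comma).
#' @return `path`, invisibly.
#' @export
writeBiomarkerTable <- function(ds, path) {
  stopifnot(is(ds, "BiomarkerDataset"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(ds@records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Parameters, objective value, fitted curve and (optionally) bootstrap
#' intervals, in a machine-readable report.
#'
#' @param fit A [FitResult-class].
#' @param path Output JSON path.
#' @param ci Optional [BootstrapInterval-class].
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, path, ci = NULL) {
  stopifnot(is(fit, "FitResult"))
  p <- fit@params
  report <- list(
    parameters = list(n0 = p@n0, r = p@r, period_days = p@periodDays,
                      onset_days = p@onsetDays),
    sse = fit@sse,
    n_evaluations = fit@nEvaluations,
    degenerate = fit@degenerate,
    onset_tied = fit@onsetTied,
    fitted_curve = fit@fittedCurve)
  if (!is.null(ci)) {
    stopifnot(is(ci, "BootstrapInterval"))
    report$bootstrap <- list(level = ci@level, B = ci@B, seed = ci@seed,
                             intervals = ci@intervals)
  }
  .writeJSON(report, path)
}
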