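#' @include AllClasses.R
NULL

#' @importFrom methods new is validObject slot setValidity show
#' @importFrom stats median
#' @importFrom withr with_seed
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml as.yaml read_yaml
NULL

# timestamped progress lines to stderr; warnings are never suppressed
.logmsg <- function(..., quiet = FALSE) {
  if (!isTRUE(quiet))
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  invisible(NULL)
}

# delimiter auto-detection among comma / tab
.detectDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
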