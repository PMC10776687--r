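#' Per-frame feature tables
#'
#' A feature table is the canonical exchange container of the package: a
#' data frame whose first column `time_ns` is strictly increasing and whose
#' remaining columns are named per-frame observables (gate distances in nm,
#' interaction energies in kJ/mol). On disk it is tab-delimited text with a
#' mandatory header row and '.' as decimal separator.
#'
#' @param time_ns numeric vector of frame times (ns), strictly increasing
#' @param ... named numeric columns, all the same length as `time_ns`
#' @return object of class `feature_table` (a data.frame)
#' @export
feature_table <- function(time_ns, ...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1]]) && !is.data.frame(cols[[1]]))
    cols <- cols[[1]]
  if (is.null(names(cols)) || any(names(cols) == ""))
    stopf("all feature columns must be named")
  n <- length(time_ns)
  if (n < 1L) stopf("feature table needs at least one frame")
  if (any(diff(time_ns) <= 0)) stopf("time_ns must be strictly increasing")
  bad <- names(cols)[vapply(cols, length, 1L) != n]
  if (length(bad)) stopf("column length mismatch: %s", paste(bad, collapse = ", "))
  out <- data.frame(time_ns = as.numeric(time_ns), cols, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d frames x %d observables (%.4g-%.4g ns)\n",
              nrow(x), ncol(x) - 1L, x$time_ns[1], x$time_ns[nrow(x)]))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Frame stride of a feature table
#'
#' @param x feature_table
#' @return frame spacing in ns (first difference; sampling must be uniform
#'   for lag-based estimators)
#' @export
frame_stride <- function(x) {
  if (nrow(x) < 2L) stopf("need >= 2 frames to define a stride")
  dt <- diff(x$time_ns)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    warnf("non-uniform frame spacing; using the first interval")
  dt[1]
}

#' Write a feature table as tab-delimited text
#'
#' @param x feature_table
#' @param path output file path
#' @export
write_feature_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read a feature table from tab-delimited text
#'
#' @param path file written by [write_feature_table()]
#' @return feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, dec = ".")
  if (names(df)[1] != "time_ns") stopf("first column must be time_ns (got '%s')", names(df)[1])
  feature_table(df$time_ns, as.list(df[-1]))
}
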