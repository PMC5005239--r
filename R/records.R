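#' Lower record samples
#'
#' A `record_sample` is a numeric vector of strictly decreasing positive
#' values, the observed lower records \eqn{x_{L(1)} > \ldots > x_{L(k)}} of
#' a sequence.  The constructor validates the record property; ties are
#' rejected because a lower record must be strictly smaller than every
#' preceding observation.
#'
#' @param x numeric vector of candidate record values.
#' @return an object of class `record_sample`.
#' @examples
#' record_sample(c(5, 3, 2))
#' @seealso [extract_lower_records()] to derive records from a raw series,
#'   [read_records()] to load them from a file.
#' @export
record_sample <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("a record sample must be nonempty", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("record values must be finite and > 0", call. = FALSE)
  bad <- which(diff(x) >= 0)
  if (length(bad))
    stop(sprintf(
      "values must be strictly decreasing; violation at positions %d and %d (%g >= %g)",
      bad[1], bad[1] + 1L, x[bad[1] + 1L], x[bad[1]]), call. = FALSE)
  structure(x, class = "record_sample")
}

#' @export
print.record_sample <- function(x, ...) {
  cat(sprintf("Lower record sample, k = %d\n", length(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Extract lower records from a raw observation series
#'
#' The first observation is always a record; each subsequent record is an
#' observation strictly smaller than every one before it (ties are not
#' records).
#'
#' @param series numeric vector of positive observations, in time order.
#' @return a [record_sample].
#' @examples
#' extract_lower_records(c(5, 7, 3, 3, 2))   # 5, 3, 2
#' @export
extract_lower_records <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 1L) stop("'series' must be nonempty", call. = FALSE)
  if (any(!is.finite(series)) || any(series <= 0))
    stop("observations must be finite and > 0", call. = FALSE)
  record_sample(series[series < c(Inf, cummin(series)[-length(series)])])
}

#' Read record values (or a raw series) from a file
#'
#' Accepts plain text with one numeric value per line, or a single-column
#' CSV with an optional header.  In `"records"` mode the values themselves
#' must be strictly decreasing lower records; in `"raw"` mode lower records
#' are extracted from the series first.
#'
#' @param path file to read.
#' @param mode `"records"` (validate as records) or `"raw"` (extract records
#'   from the series).
#' @return a [record_sample].
#' @examples
#' f <- system.file("extdata", "la_rainfall_records.txt", package = "ehldrec")
#' read_records(f)
#' @export
read_records <- function(path, mode = c("records", "raw")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub(",.*$", "", lines))  # tolerate trailing CSV columns
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- which(keep)
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) && is.na(vals[1]) && !is.na(suppressWarnings(
      as.numeric(lines[min(2, length(lines))])))) {
    # single header line such as "value"
    vals <- vals[-1]; lineno <- lineno[-1]
  }
  if (any(is.na(vals)))
    stop(sprintf("non-numeric value on line %d: '%s'",
                 lineno[which(is.na(vals))[1]],
                 lines[which(is.na(vals))[1]]), call. = FALSE)
  if (!length(vals)) stop("no values found in ", path, call. = FALSE)
  if (mode == "raw") extract_lower_records(vals) else record_sample(vals)
}

as_record_sample <- function(x) {
  if (inherits(x, "record_sample")) x else record_sample(x)
}
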