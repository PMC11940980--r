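#' @importFrom data.table data.table as.data.table setDT setkey setkeyv rbindlist
#'   fifelse fcase setorder setorderv setcolorder copy setnames := .N .SD .GRP
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Number of days between two calendar dates
#'
#' All durations in this package are integer day counts; this helper is the one
#' place date subtraction happens, so the day-count convention is centralized.
#' `days_between(a, b)` is positive when `b` is after `a`.
#'
#' @param from,to `Date` vectors.
#' @return Integer vector of day differences (`to - from`).
#' @export
days_between <- function(from, to) {
  as.integer(as.Date(to)) - as.integer(as.Date(from))
}

#' Inclusive day count of a date interval
#'
#' The length of `[start, end]` counting both endpoints, the convention used for
#' treatment durations and costing windows throughout the pipeline.
#'
#' @param start,end `Date` vectors, `end >= start`.
#' @return Integer vector, `end - start + 1`.
#' @export
interval_days <- function(start, end) {
  days_between(start, end) + 1L
}

as_date_safe <- function(x) {
  if (inherits(x, "Date")) return(x)
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

pmin_date <- function(...) {
  args <- list(...)
  out <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), args)
  as.Date(out, origin = "1970-01-01")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
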