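# Wall-clock timestamp handling.
#
# All timestamps are ISO 8601 local wall-clock to minute precision
# (YYYY-MM-DDTHH:MM) without a zone offset. They are represented internally
# as POSIXct pinned to UTC so that calendar-day arithmetic (the midnight
# anchoring of the interval grid) is exact and daylight-saving transitions
# cannot shift a midnight.

#' Parse ISO 8601 wall-clock timestamps
#'
#' @param x character vector of `YYYY-MM-DDTHH:MM` strings (seconds are
#'   accepted and truncated).
#' @return POSIXct vector (UTC-pinned wall clock). Unparseable entries are NA.
#' @keywords internal
parse_ts <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  # tolerate trailing seconds
  retry <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  out
}

#' Format timestamps back to the minute-precision ISO form
#' @param x POSIXct vector.
#' @keywords internal
format_ts <- function(x) format(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

#' Midnight at the start of the calendar day containing `x`
#' @keywords internal
floor_day <- function(x) as.POSIXct(trunc(x, units = "days"), tz = "UTC")

#' Positive-duration overlap of [s1, e1) with [s2, e2)
#'
#' The half-open convention is used everywhere: a span ending exactly where
#' another starts does not overlap it.
#' @keywords internal
spans_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}
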