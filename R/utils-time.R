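#' @keywords internal
"_PACKAGE"

# All timestamps in the package are timezone-naive local clock time,
# represented internally as POSIXct with tz = "UTC" (a neutral carrier: no
# DST, no offset arithmetic). Files use ISO-8601 minute precision.

MT_FMT <- "%Y-%m-%dT%H:%M"

#' Parse ISO-8601 minute-precision timestamps
#'
#' Accepts `YYYY-MM-DDTHH:MM` or `YYYY-MM-DD HH:MM` (optionally with
#' seconds, which are truncated). Returns POSIXct carried in UTC; values
#' are interpreted as naive local clock time.
#'
#' @param x character vector.
#' @return POSIXct vector; unparsable entries are `NA`.
#' @keywords internal
mt_parse <- function(x) {
  x <- as.character(x)
  x2 <- sub("T", " ", x, fixed = TRUE)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  ok <- !is.na(x2) & nzchar(x2)
  p1 <- as.POSIXct(x2[ok], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  p2 <- as.POSIXct(x2[ok], tz = "UTC", format = "%Y-%m-%d %H:%M")
  out[ok] <- ifelse(is.na(p1), as.numeric(p2), as.numeric(p1))
  # truncate to the minute
  as.POSIXct(floor(as.numeric(out) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

#' @keywords internal
mt_format <- function(t) format(t, MT_FMT, tz = "UTC")

#' @keywords internal
mt_date <- function(t) as.Date(t, tz = "UTC")

#' Minutes since local midnight
#' @keywords internal
mt_minute_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60L + lt$min
}

#' Day anchor (midnight) of a timestamp
#' @keywords internal
mt_midnight <- function(t) {
  as.POSIXct(as.numeric(t) - mt_minute_of_day(t) * 60 -
               as.POSIXlt(t, tz = "UTC")$sec,
             origin = "1970-01-01", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted mean / variance / Pearson correlation
#' @keywords internal
wtd_mean <- function(x, w) sum(w * x) / sum(w)

#' @keywords internal
wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' @keywords internal
wtd_cor <- function(x, y, w) {
  mx <- wtd_mean(x, w); my <- wtd_mean(y, w)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}
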