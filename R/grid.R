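#' Clock-aligned interval grid
#'
#' Defines the fixed grid of half-open windows `[start, start + period)` on
#' which distribution characteristics are computed. The grid is anchored at a
#' midnight origin so that interval `i` maps to clock slot `t = i mod T` and
#' day `d = i div T`, with `T` intervals per day (144, 48 or 24 for 10, 30 or
#' 60 min windows). Anchoring at midnight keeps clock slots aligned across
#' days, which the day-offset baselines of the acceleration indices require.
#'
#' @param period_minutes window length in minutes; one of 10, 30, 60.
#' @param origin grid origin; coerced to the midnight (UTC) of the supplied
#'   day. Conventionally the midnight of the housing day.
#' @return an object of class `interval_grid` with fields `period_minutes`,
#'   `intervals_per_day` and `origin`.
#' @examples
#' g <- interval_grid(60, "2014-01-01")
#' interval_index(g, as.POSIXct("2014-01-02 06:30:00", tz = "UTC"))
#' @export
interval_grid <- function(period_minutes, origin) {
  if (!period_minutes %in% c(10L, 30L, 60L))
    stop("period_minutes must be one of 10, 30, 60", call. = FALSE)
  origin <- midnight_of(origin)
  structure(
    list(period_minutes = as.integer(period_minutes),
         intervals_per_day = as.integer(1440L / period_minutes),
         origin = origin),
    class = "interval_grid")
}

#' Interval index of a timestamp
#'
#' @param grid an [interval_grid()].
#' @param time POSIXct vector.
#' @return integer vector of 0-based interval indices on the continuous
#'   timeline starting at the grid origin.
#' @export
interval_index <- function(grid, time) {
  stopifnot(inherits(grid, "interval_grid"))
  per <- grid$period_minutes * 60
  as.integer(floor((as.numeric(as_utc(time)) - as.numeric(grid$origin)) / per))
}

#' Start time of an interval
#'
#' @param grid an [interval_grid()].
#' @param i integer interval index (0-based), vectorised.
#' @return POSIXct start of the half-open interval.
#' @export
interval_start <- function(grid, i) {
  stopifnot(inherits(grid, "interval_grid"))
  grid$origin + i * grid$period_minutes * 60
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid> %d min (%d/day), origin %s\n",
              x$period_minutes, x$intervals_per_day, format_utc(x$origin)))
  invisible(x)
}
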