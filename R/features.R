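#' Distribution characteristics of the total-acceleration magnitude
#'
#' The detector consumes per-window summary statistics ("distribution
#' characteristics") of the total-acceleration magnitude
#' `s_t = sqrt(x_t^2 + y_t^2 + z_t^2)`. Characteristics that track signal
#' fluctuation (standard deviation, variance, and the p-variation of order
#' 1-3) carry the circadian/nest-building signal; location-type
#' characteristics (mean, median, percentiles, max) show no regular temporal
#' pattern for ear-tag data and are excluded from detection by default, but
#' remain computable.
#'
#' @name characteristics
NULL

ALL_CHARACTERISTICS <- c("mean", "std", "variance", "skewness", "kurtosis",
                         "median", "p25", "p75", "max",
                         "variation1", "variation2", "variation3")

#' All supported distribution characteristics
#' @return character vector of the twelve characteristic names.
#' @export
all_characteristics <- function() ALL_CHARACTERISTICS

#' Default (fluctuation) characteristic set used for detection
#' @return character vector: std, variance, variation1, variation2, variation3.
#' @export
fluctuation_characteristics <- function()
  c("std", "variance", "variation1", "variation2", "variation3")

#' Total-acceleration magnitude
#'
#' Euclidean norm of a triaxial sample, removing orientation dependence.
#'
#' @param x,y,z acceleration components in g (vectorised).
#' @return `sqrt(x^2 + y^2 + z^2)`, always >= 0.
#' @export
magnitude <- function(x, y, z) {
  if (!all(is.finite(x), is.finite(y), is.finite(z)))
    stop("magnitude: inputs must be finite", call. = FALSE)
  sqrt(x^2 + y^2 + z^2)
}

#' p-variation of a window
#'
#' Sum of p-th powers of absolute consecutive-sample differences,
#' `sum_i |s_(i+1) - s_i|^p`, over the stored samples of a window in timestamp
#' order. Differences are taken between consecutive *stored* observations,
#' also across dropout gaps; no gap normalisation is applied. With fewer than
#' two samples the statistic is undefined and `NA` is returned.
#'
#' @param window_samples numeric vector, ordered by timestamp.
#' @param p order, one of 1, 2, 3.
#' @return non-negative scalar, or `NA_real_` for fewer than 2 samples.
#' @export
p_variation <- function(window_samples, p) {
  if (!p %in% 1:3) stop("p must be 1, 2 or 3", call. = FALSE)
  if (length(window_samples) < 2L) return(NA_real_)
  sum(abs(diff(window_samples))^p)
}

# Single-window statistic dispatcher. `x` is the vector of magnitudes within
# the window in timestamp order; returns NA below min_obs.
window_stat <- function(x, characteristic, min_obs = 2L) {
  n <- length(x)
  if (n < min_obs) return(NA_real_)
  switch(characteristic,
    mean = mean(x),
    std = sqrt(var(x)),
    variance = var(x),
    skewness = {
      m <- mean(x); m2 <- mean((x - m)^2)
      if (m2 <= 0) NA_real_ else mean((x - m)^3) / m2^1.5
    },
    kurtosis = {
      m <- mean(x); m2 <- mean((x - m)^2)
      if (m2 <= 0) NA_real_ else mean((x - m)^4) / m2^2 - 3
    },
    median = median(x),
    p25 = quantile(x, 0.25, names = FALSE, type = 7),
    p75 = quantile(x, 0.75, names = FALSE, type = 7),
    max = max(x),
    variation1 = p_variation(x, 1L),
    variation2 = p_variation(x, 2L),
    variation3 = p_variation(x, 3L),
    stop(sprintf("unknown characteristic '%s'", characteristic), call. = FALSE))
}

#' Construct a feature series
#'
#' A `feature_series` holds one distribution characteristic on a clock-aligned
#' grid: position `p` of `values` is interval index `p - 1` (0-based from the
#' grid origin). Intervals with fewer than `min_obs` stored samples are `NA`.
#'
#' @param sow_id character identifier.
#' @param characteristic one of [all_characteristics()].
#' @param grid an [interval_grid()].
#' @param values numeric vector over intervals `0 .. length(values) - 1`.
#' @param n_obs integer vector of per-interval stored-sample counts.
#' @return an object of class `feature_series`.
#' @export
feature_series <- function(sow_id, characteristic, grid, values,
                           n_obs = rep(NA_integer_, length(values))) {
  stopifnot(inherits(grid, "interval_grid"),
            characteristic %in% ALL_CHARACTERISTICS,
            length(values) == length(n_obs))
  structure(list(sow_id = sow_id, characteristic = characteristic, grid = grid,
                 values = as.numeric(values), n_obs = as.integer(n_obs)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> sow %s, %s, %d min grid, %d intervals (%d defined)\n",
              x$sow_id, x$characteristic, x$grid$period_minutes,
              length(x$values), sum(!is.na(x$values))))
  invisible(x)
}

#' Compute windowed distribution characteristics
#'
#' Partitions the stored samples into the half-open grid intervals
#' `[start, start + period)` and computes the requested characteristics of the
#' total-acceleration magnitude per interval, together with the stored-sample
#' count `n_obs`. Intervals with fewer than `min_obs` samples are missing.
#'
#' @param series an `accel_series`.
#' @param grid an [interval_grid()]; samples must not precede the grid origin.
#' @param characteristics subset of [all_characteristics()]; defaults to the
#'   fluctuation set used for detection.
#' @param min_obs minimum stored samples for a defined value (default 2, the
#'   minimum for any difference-based statistic).
#' @return named list of `feature_series`, one per characteristic, covering
#'   intervals 0 .. last observed interval.
#' @export
compute_features <- function(series, grid,
                             characteristics = fluctuation_characteristics(),
                             min_obs = 2L) {
  stopifnot(inherits(series, "accel_series"), inherits(grid, "interval_grid"))
  characteristics <- match.arg(characteristics, ALL_CHARACTERISTICS,
                               several.ok = TRUE)
  d <- series$data
  if (nrow(d) == 0L) {
    out <- lapply(characteristics, function(ch)
      feature_series(series$sow_id, ch, grid, numeric(0), integer(0)))
    names(out) <- characteristics
    return(out)
  }
  m <- magnitude(d$x, d$y, d$z)
  idx <- interval_index(grid, d$timestamp)
  if (any(idx < 0L))
    stop("samples precede the grid origin; anchor the grid at the housing day",
         call. = FALSE)
  dtm <- data.table(interval = idx, m = m)
  agg <- dtm[, {
    v <- m
    st <- lapply(characteristics, function(ch) window_stat(v, ch, min_obs))
    names(st) <- characteristics
    c(list(n_obs = .N), st)
  }, keyby = interval]

  n_int <- max(idx) + 1L
  n_obs <- integer(n_int)
  n_obs[agg$interval + 1L] <- agg$n_obs
  out <- lapply(characteristics, function(ch) {
    vals <- rep(NA_real_, n_int)
    vals[agg$interval + 1L] <- agg[[ch]]
    feature_series(series$sow_id, ch, grid, vals, n_obs)
  })
  names(out) <- characteristics
  out
}

#' Compute one characteristic over an arbitrary window
#'
#' Same statistic definitions as [compute_features()], applied to the stored
#' samples with timestamps in `[start, end)`. Used by the `Over` index, whose
#' windows extend beyond the grid intervals.
#'
#' @param series an `accel_series`.
#' @param start,end window bounds (POSIXct), `start < end`.
#' @param characteristic one of [all_characteristics()].
#' @param min_obs minimum stored samples for a defined value.
#' @return scalar value or `NA_real_`.
#' @export
compute_feature_on_window <- function(series, start, end, characteristic,
                                      min_obs = 2L) {
  stopifnot(inherits(series, "accel_series"))
  start <- as_utc(start); end <- as_utc(end)
  if (!(start < end)) stop("start must precede end", call. = FALSE)
  ts <- as.numeric(series$data$timestamp)
  sel <- ts >= as.numeric(start) & ts < as.numeric(end)
  if (!any(sel)) return(NA_real_)
  d <- series$data[sel]
  window_stat(magnitude(d$x, d$y, d$z), characteristic, min_obs)
}
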