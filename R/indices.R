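#' Acceleration indices: circadian cancellation and accumulation
#'
#' An acceleration index transforms a characteristic series so that the
#' circadian rhythm cancels whenever consecutive days resemble each other,
#' while sustained pre-farrowing deviations accumulate. The baseline for
#' interval `i` is the moving average of the same clock slot one day earlier:
#' `B_r(i) = mean of defined F over intervals (i - T - r) .. (i - T + r)`,
#' a symmetric `(2r + 1)`-interval window on the continuous timeline (it may
#' cross midnight). Seven indices are supported: `Orig` (passthrough), `Diff`
#' (`F - B`), `Quot` (`F / B`), `Over` (quotient on overlap-extended windows),
#' `CumDi` (running sum of Diff), `CumQ` (running sum of Quot) and `CumAv`
#' (running sum of deviations from the trailing one-day mean).
#'
#' @name indices
NULL

MA_RANGES <- list(`10` = c(1L, 5L, 9L, 13L, 19L, 25L),
                  `30` = c(1L, 3L, 5L, 9L),
                  `60` = c(1L, 3L, 5L))
OVERLAP_MINUTES <- c(`10` = 2L, `30` = 5L, `60` = 10L)

#' Admissible moving-average ranges for a window length
#'
#' @param period_minutes 10, 30 or 60.
#' @return integer vector of admissible half-widths `r`.
#' @export
ma_ranges_for <- function(period_minutes) {
  p <- as.character(period_minutes)
  if (!p %in% names(MA_RANGES))
    stop("period_minutes must be one of 10, 30, 60", call. = FALSE)
  MA_RANGES[[p]]
}

#' Overlap (minutes) of the Over index for a window length
#'
#' @param period_minutes 10, 30 or 60.
#' @return overlap in minutes: 2, 5 or 10.
#' @export
overlap_for <- function(period_minutes) {
  p <- as.character(period_minutes)
  if (!p %in% names(OVERLAP_MINUTES))
    stop("period_minutes must be one of 10, 30, 60", call. = FALSE)
  unname(OVERLAP_MINUTES[p])
}

INDEX_TYPES <- c("Orig", "Diff", "Quot", "Over", "CumDi", "CumQ", "CumAv")

#' Supported acceleration index types
#' @return character vector of the seven index names.
#' @export
index_types <- function() INDEX_TYPES

# Indices with a day-offset moving-average baseline (take an r).
BASELINE_INDEX_TYPES <- c("Diff", "Quot", "Over", "CumDi", "CumQ")

assert_ma_range <- function(period_minutes, r) {
  if (!r %in% ma_ranges_for(period_minutes))
    stop_invariant("r admissible for period",
                   "r = %s not in {%s} for %d min", format(r),
                   paste(ma_ranges_for(period_minutes), collapse = ", "),
                   period_minutes)
  as.integer(r)
}

index_series <- function(feature, index_type, ma_range, values) {
  structure(list(sow_id = feature$sow_id, characteristic = feature$characteristic,
                 index_type = index_type, ma_range = ma_range,
                 grid = feature$grid, values = as.numeric(values)),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("<index_series> sow %s, %s(%s), r=%s, %d min grid, %d intervals (%d defined)\n",
              x$sow_id, x$index_type, x$characteristic,
              ifelse(is.na(x$ma_range), "-", x$ma_range), x$grid$period_minutes,
              length(x$values), sum(!is.na(x$values))))
  invisible(x)
}

# Windowed mean of defined values over positions (p - T - r) .. (p - T + r);
# NA where the window is not fully on the timeline (i < T + r) or fewer than
# r + 1 of its 2r + 1 entries are defined. Each window mean is computed
# directly (not via prefix sums) so it is the plain mean of the window
# values, bit-for-bit.
baseline_values <- function(values, T_day, r) {
  n <- length(values)
  out <- rep(NA_real_, n)
  first <- T_day + r + 1L
  if (first > n) return(out)
  for (p in first:n) {
    w <- values[(p - T_day - r):(p - T_day + r)]
    w <- w[!is.na(w)]
    if (length(w) >= r + 1L) out[p] <- mean(w)   # ceil((2r+1)/2) = r + 1
  }
  out
}

#' Day-offset moving-average baseline
#'
#' Mean of the defined feature values over the `(2r + 1)` intervals centred on
#' the same clock slot one day earlier. Missing if interval `i < T + r` (no
#' previous day) or if fewer than `ceil((2r + 1) / 2)` window entries are
#' defined.
#'
#' @param feature a `feature_series`.
#' @param i 0-based interval index (vectorised).
#' @param r moving-average half-width, admissible for the grid period.
#' @return numeric vector of baselines (NA where undefined).
#' @export
baseline_ma <- function(feature, i, r) {
  stopifnot(inherits(feature, "feature_series"))
  r <- assert_ma_range(feature$grid$period_minutes, r)
  b <- baseline_values(feature$values, feature$grid$intervals_per_day, r)
  out <- rep(NA_real_, length(i))
  inside <- i >= 0L & i < length(b)
  out[inside] <- b[i[inside] + 1L]
  out
}

# Division guard: variance-type features can be exactly 0 in quiet intervals.
EPS_BASELINE <- 1e-12

#' Diff index: day-offset difference
#'
#' `Diff(i) = F(i) - B_r(i)`; missing where either side is missing. Centred on
#' zero when consecutive days are similar, insensitive to the sow's absolute
#' activity level.
#'
#' @param feature a `feature_series`.
#' @param r moving-average half-width.
#' @return an `index_series`.
#' @export
diff_index <- function(feature, r) {
  r <- assert_ma_range(feature$grid$period_minutes, r)
  b <- baseline_values(feature$values, feature$grid$intervals_per_day, r)
  index_series(feature, "Diff", r, feature$values - b)
}

#' Quot index: day-offset quotient
#'
#' `Quot(i) = F(i) / B_r(i)`; missing where the baseline is missing or its
#' absolute value falls below `1e-12` (guarded division; never +/-Inf). Close
#' to 1 when consecutive days are similar.
#'
#' @inheritParams diff_index
#' @return an `index_series`.
#' @export
quot_index <- function(feature, r) {
  r <- assert_ma_range(feature$grid$period_minutes, r)
  b <- baseline_values(feature$values, feature$grid$intervals_per_day, r)
  b[!is.na(b) & abs(b) < EPS_BASELINE] <- NA_real_
  index_series(feature, "Quot", r, feature$values / b)
}

#' Over index: quotient on overlap-extended windows
#'
#' Like `Quot`, but both the numerator and each baseline window are extended
#' by the period-specific overlap `o` (10/5/2 min for 60/30/10 min windows) on
#' both ends, absorbing short shifts of activity across interval boundaries.
#' The numerator for interval `i` is the characteristic over
#' `[start(i) - o, end(i) + o)` and the denominator is the day-offset moving
#' average of the same extended-window characteristic. Requires the raw
#' samples, since the extended windows are not part of the interval grid.
#'
#' @param series the raw `accel_series`.
#' @param characteristic one of [all_characteristics()].
#' @param grid an [interval_grid()].
#' @param r moving-average half-width.
#' @param overlap_minutes overlap `o`; defaults to the period-specific value.
#'   `0` reduces Over to Quot (useful for testing).
#' @param min_obs minimum stored samples per extended window.
#' @return an `index_series`.
#' @export
over_index <- function(series, characteristic, grid, r,
                       overlap_minutes = overlap_for(grid$period_minutes),
                       min_obs = 2L) {
  ext <- extended_feature_values(series, characteristic, grid,
                                 overlap_minutes, min_obs)
  f <- feature_series(series$sow_id, characteristic, grid, ext$values, ext$n_obs)
  out <- quot_index(f, r)
  out$index_type <- "Over"
  out
}

# Characteristic over [start(i) - o, end(i) + o) for every interval of the
# series' span; binary search on the sorted timestamps.
extended_feature_values <- function(series, characteristic, grid,
                                    overlap_minutes, min_obs = 2L) {
  stopifnot(inherits(series, "accel_series"), inherits(grid, "interval_grid"))
  d <- series$data
  if (nrow(d) == 0L) return(list(values = numeric(0), n_obs = integer(0)))
  ts <- as.numeric(d$timestamp)
  m <- magnitude(d$x, d$y, d$z)
  per <- grid$period_minutes * 60
  o <- overlap_minutes * 60
  n_int <- max(interval_index(grid, d$timestamp)) + 1L
  starts <- as.numeric(grid$origin) + (seq_len(n_int) - 1L) * per - o
  ends <- starts + per + 2 * o
  # first sample index >= start, last sample index < end
  lo <- findInterval(starts - 0.5, ts) + 1L
  hi <- findInterval(ends - 0.5, ts)
  vals <- rep(NA_real_, n_int)
  nobs <- pmax(hi - lo + 1L, 0L)
  for (p in seq_len(n_int)) {
    if (nobs[p] >= min_obs)
      vals[p] <- window_stat(m[lo[p]:hi[p]], characteristic, min_obs)
  }
  list(values = vals, n_obs = as.integer(nobs))
}

# Running sum of `x` with missing terms contributing 0, NA before the first
# defined term. Accumulation starts at the first defined interval after
# housing and is never reset at day boundaries. Plain term-by-term loop so
# the partial sums are the literal sequential sums.
running_sum_skip_na <- function(x) {
  def <- !is.na(x)
  if (!any(def)) return(rep(NA_real_, length(x)))
  first <- which(def)[1L]
  out <- rep(NA_real_, length(x))
  acc <- 0
  for (i in first:length(x)) {
    if (def[i]) acc <- acc + x[i]
    out[i] <- acc
  }
  out
}

#' CumDi index: cumulative sum of Diff
#'
#' `CumDi(i) = sum_(j <= i) Diff(j)` over defined Diff values, accumulated
#' from the first defined interval; missing terms contribute 0 and the sum is
#' never reset. Drifts near a constant when days are similar and climbs
#' steeply once activity exceeds the previous day.
#'
#' @inheritParams diff_index
#' @return an `index_series`.
#' @export
cumdi_index <- function(feature, r) {
  d <- diff_index(feature, r)
  index_series(feature, "CumDi", d$ma_range, running_sum_skip_na(d$values))
}

#' CumQ index: cumulative sum of Quot
#'
#' Running sum of `Quot` from its first defined interval. Increases with slope
#' about 1 while days are similar (`Quot` near 1) and accelerates sharply just
#' before the onset of farrowing.
#'
#' @inheritParams diff_index
#' @return an `index_series`.
#' @export
cumq_index <- function(feature, r) {
  q <- quot_index(feature, r)
  index_series(feature, "CumQ", q$ma_range, running_sum_skip_na(q$values))
}

#' CumAv index: cumulative deviation from the trailing one-day mean
#'
#' `CumAv(i) = sum_(j <= i) [F(j) - mean of F over the T intervals preceding
#' j]` with `T` = 24, 48 or 144 for 60, 30 or 10 min windows (exactly one
#' day). Terms with missing `F`, incomplete trailing history (`j < T`) or
#' fewer than `ceil(T / 2)` defined trailing values contribute 0.
#'
#' @param feature a `feature_series`.
#' @return an `index_series` (no moving-average range).
#' @export
cumav_index <- function(feature) {
  v <- feature$values
  T_day <- feature$grid$intervals_per_day
  n <- length(v)
  term <- rep(NA_real_, n)
  if (n > T_day) {
    for (p in (T_day + 1L):n) {
      if (is.na(v[p])) next
      w <- v[(p - T_day):(p - 1L)]
      w <- w[!is.na(w)]
      if (length(w) >= ceiling(T_day / 2)) term[p] <- v[p] - mean(w)
    }
  }
  index_series(feature, "CumAv", NA_integer_, running_sum_skip_na(term))
}

#' Orig index: untransformed passthrough
#'
#' The characteristic series itself, monitored without circadian cancellation.
#' Unlike the transformed indices it needs no previous-day data.
#'
#' @param feature a `feature_series`.
#' @return an `index_series`.
#' @export
orig_index <- function(feature) {
  index_series(feature, "Orig", NA_integer_, feature$values)
}

#' Compute an acceleration index
#'
#' Dispatcher over the seven index types. `Over` needs the raw series.
#'
#' @param feature a `feature_series` (ignored for `Over` if `raw` given with
#'   `characteristic`/`grid` taken from `feature`).
#' @param index_type one of [index_types()].
#' @param ma_range half-width `r`; required for Diff, Quot, Over, CumDi, CumQ.
#' @param raw the raw `accel_series`; required for `Over`.
#' @param ... passed on (e.g. `overlap_minutes`, `min_obs` for `Over`).
#' @return an `index_series`.
#' @export
compute_index <- function(feature, index_type, ma_range = NULL, raw = NULL, ...) {
  index_type <- match.arg(index_type, INDEX_TYPES)
  if (index_type %in% BASELINE_INDEX_TYPES && is.null(ma_range))
    stop(sprintf("index %s requires ma_range", index_type), call. = FALSE)
  switch(index_type,
    Orig = orig_index(feature),
    Diff = diff_index(feature, ma_range),
    Quot = quot_index(feature, ma_range),
    CumDi = cumdi_index(feature, ma_range),
    CumQ = cumq_index(feature, ma_range),
    CumAv = cumav_index(feature),
    Over = {
      if (is.null(raw)) stop("index Over requires the raw accel_series", call. = FALSE)
      over_index(raw, feature$characteristic, feature$grid, ma_range, ...)
    })
}
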