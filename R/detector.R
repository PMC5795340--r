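#' One-sided CUSUM detection of the farrowing onset
#'
#' The monitored statistic `X_i` is an acceleration index per interval. The
#' chart accumulates positive deviations beyond an allowance above the
#' in-control mean: `C+_i = max(0, X_i - (mu0 + kappa) + C+_(i-1))`, starting
#' at 0, and alarms at the first exceedance of the control limit
#' `CL = sigma * h`. `mu0` and `sigma` are the sow-individual mean and sample
#' standard deviation of the index over a parameterization period of one or
#' two reference days (Day -4, Day -5, or both, relative to the calculated
#' farrowing date); alarms are expected within the prediction period Days -3
#' through 0.
#'
#' @name detector
NULL

EPS_SIGMA <- 1e-9

#' Allowance-value (k) grid
#'
#' The standard grid evaluated for the allowance value:
#' 0.1, 0.25, 0.5, then 1 to 12.5 in steps of 0.5, then 15, 20, 25, 30.
#' @return numeric vector of 31 values.
#' @export
cusum_k_grid <- function() c(0.1, 0.25, 0.5, seq(1, 12.5, by = 0.5), 15, 20, 25, 30)

#' Smoothing-value (h) grid
#'
#' Control-limit multipliers 4 through 10.
#' @return integer vector 4:10.
#' @export
cusum_h_grid <- function() 4:10

PARAM_SCENARIOS <- c("m4", "m5", "m45")

scenario_days <- function(scenario) {
  switch(scenario, m4 = 4L, m5 = 5L, m45 = c(4L, 5L),
         stop(sprintf("unknown parameterization scenario '%s'", scenario),
              call. = FALSE))
}

#' Fit sow-individual CUSUM parameters
#'
#' Estimates `mu0` (mean) and `sigma` (sample s.d., n - 1 denominator) of the
#' index over the chosen parameterization day(s), where Day -n is the 24 h
#' block `[calculated_farrowing - n days, calculated_farrowing - (n-1) days)`
#' and an interval belongs to a day if its start falls inside the block.
#' `sigma` is floored at `1e-9` (flagged via `sigma_floored`) to avoid a
#' degenerate zero control limit.
#'
#' @param index an `index_series`.
#' @param calculated_farrowing calculated farrowing date (midnight, Day 0).
#' @param scenario `"m4"` (Day -4), `"m5"` (Day -5) or `"m45"` (both days
#'   pooled).
#' @param k allowance value (> 0), typically from [cusum_k_grid()].
#' @param h smoothing value defining the control limit `sigma * h`.
#' @param k_mode `"standardized"` (default): the allowance is `kappa = k *
#'   sigma`, so one k grid is comparable across indices of very different
#'   scales; `"raw"`: `kappa = k` on the index scale.
#' @return an object of class `cusum_params`.
#' @export
fit_cusum_params <- function(index, calculated_farrowing,
                             scenario = c("m4", "m5", "m45"),
                             k = 3, h = 5,
                             k_mode = c("standardized", "raw")) {
  stopifnot(inherits(index, "index_series"))
  scenario <- match.arg(scenario)
  k_mode <- match.arg(k_mode)
  if (!is.numeric(k) || k <= 0) stop_invariant("k > 0", "got %s", format(k))
  if (!is.numeric(h) || h < 0) stop_invariant("h >= 0", "got %s", format(h))
  cf <- midnight_of(calculated_farrowing)
  vals <- index_values_in(index, param_window(cf, scenario))
  if (length(vals) == 0L)
    stop(sprintf("unparameterizable sow %s: no defined %s(%s) values in scenario %s",
                 index$sow_id, index$index_type, index$characteristic, scenario),
         call. = FALSE)
  mu0 <- mean(vals)
  sigma <- if (length(vals) >= 2L) sd(vals) else 0
  floored <- !is.finite(sigma) || sigma < EPS_SIGMA
  if (floored) sigma <- EPS_SIGMA
  structure(list(sow_id = index$sow_id, mu0 = mu0, sigma = sigma,
                 sigma_floored = floored, k = k, h = h, k_mode = k_mode,
                 scenario = scenario, calculated_farrowing = cf,
                 control_limit = sigma * h, n_param = length(vals)),
            class = "cusum_params")
}

# list of c(start, end) numeric windows for the scenario's day blocks
param_window <- function(cf, scenario) {
  lapply(scenario_days(scenario), function(n) {
    s <- as.numeric(cf) - n * 86400
    c(s, s + 86400)
  })
}

index_values_in <- function(index, windows) {
  starts <- as.numeric(interval_start(index$grid, seq_along(index$values) - 1L))
  sel <- Reduce(`|`, lapply(windows, function(w) starts >= w[1L] & starts < w[2L]))
  v <- index$values[sel]
  v[!is.na(v)]
}

#' @export
print.cusum_params <- function(x, ...) {
  cat(sprintf("<cusum_params> sow %s, %s: mu0 = %.4g, sigma = %.4g%s (n = %d)\n  k = %g (%s), h = %g, CL = %.4g\n",
              x$sow_id, x$scenario, x$mu0, x$sigma,
              if (x$sigma_floored) " [floored]" else "", x$n_param,
              x$k, x$k_mode, x$h, x$control_limit))
  invisible(x)
}

# The plain recursion; kept as a tight scalar loop so the trajectory is the
# literal term-by-term sum (no reassociation).
cusum_recursion <- function(x, threshold) {
  n <- length(x)
  out <- numeric(n)
  c_prev <- 0
  for (i in seq_len(n)) {
    xi <- x[i]
    if (!is.na(xi)) c_prev <- max(0, xi - threshold + c_prev)
    out[i] <- c_prev
  }
  out
}

#' Run the one-sided CUSUM chart
#'
#' Applies the recursion `C+_i = max(0, X_i - (mu0 + kappa) + C+_(i-1))` to
#' the index values whose interval start lies in `[start, end)`, beginning
#' with `C+ = 0` before the first defined value. Missing index values freeze
#' the chart (carry `C+` forward) so sensor outages neither generate nor
#' suppress alarms. Alarms are the intervals with `C+ > CL` (strict
#' exceedance); only the first is used for evaluation. In evaluation mode
#' `end` is the true onset so post-onset alarms cannot arise; in deployment
#' `end` is the series end.
#'
#' @param index an `index_series`.
#' @param params a `cusum_params` from [fit_cusum_params()].
#' @param start chart start; defaults to Day -3 00:00 relative to the
#'   calculated farrowing date (the parameterization period is excluded from
#'   charting).
#' @param end chart end (exclusive); defaults to the series end.
#' @return an object of class `cusum_result` with the trajectory table
#'   (`interval`, `time`, `x`, `cusum`, `alarm`), `alarms` (interval indices)
#'   and `first_alarm` (interval index or `NA`).
#' @export
run_cusum <- function(index, params, start = NULL, end = NULL) {
  stopifnot(inherits(index, "index_series"), inherits(params, "cusum_params"))
  if (is.null(start)) start <- params$calculated_farrowing - 3 * 86400
  start <- as_utc(start)
  n_all <- length(index$values)
  starts <- as.numeric(interval_start(index$grid, seq_len(n_all) - 1L))
  end_num <- if (is.null(end)) Inf else as.numeric(as_utc(end))
  if (as.numeric(start) >= end_num) stop("start must precede end", call. = FALSE)
  sel <- which(starts >= as.numeric(start) & starts < end_num)
  x <- index$values[sel]
  kappa <- if (params$k_mode == "standardized") params$k * params$sigma else params$k
  traj <- cusum_recursion(x, params$mu0 + kappa)
  cl <- params$control_limit
  alarm <- traj > cl
  intervals <- sel - 1L
  tab <- data.table(interval = intervals,
                    time = as.POSIXct(starts[sel], origin = "1970-01-01", tz = "UTC"),
                    x = x, cusum = traj, control_limit = cl, alarm = alarm)
  alarms <- intervals[alarm]
  structure(list(sow_id = index$sow_id, params = params, grid = index$grid,
                 index_type = index$index_type,
                 characteristic = index$characteristic,
                 ma_range = index$ma_range, trajectory = tab, alarms = alarms,
                 first_alarm = if (length(alarms)) alarms[1L] else NA_integer_),
            class = "cusum_result")
}

#' @export
print.cusum_result <- function(x, ...) {
  cat(sprintf("<cusum_result> sow %s, %s(%s): %d intervals, %d alarms%s\n",
              x$sow_id, x$index_type, x$characteristic, nrow(x$trajectory),
              length(x$alarms),
              if (is.na(x$first_alarm)) "" else
                sprintf(", first at %s",
                        format_utc(interval_start(x$grid, x$first_alarm)))))
  invisible(x)
}

#' Offset of the first alarm relative to the true onset
#'
#' @param result a `cusum_result`.
#' @param true_onset true onset of farrowing.
#' @return hours between the start of the first alarm interval and the true
#'   onset (negative = alarm before onset), or `NA_real_` if no alarm.
#' @export
first_alarm_offset <- function(result, true_onset) {
  stopifnot(inherits(result, "cusum_result"))
  if (is.na(result$first_alarm)) return(NA_real_)
  at <- interval_start(result$grid, result$first_alarm)
  as.numeric(difftime(at, as_utc(true_onset), units = "hours"))
}
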