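# Independent oracles and fixture builders. Oracles share only elementary
# reductions (sum, mean, var, quantile) with the package; partitioning,
# windowing, missing-value handling and recursions are re-derived here.

UTC <- "UTC"
T0 <- as.POSIXct("2014-01-08 00:00:00", tz = UTC)   # housing-day midnight
CF <- as.POSIXct("2014-01-15 00:00:00", tz = UTC)   # calculated farrowing

# --- independent per-window statistic --------------------------------------
oracle_stat <- function(x, characteristic) {
  n <- length(x)
  switch(characteristic,
    mean = mean(x),
    std = sqrt(var(x)),
    variance = var(x),
    skewness = e1071::skewness(x, type = 1),
    kurtosis = e1071::kurtosis(x, type = 1),
    median = unname(quantile(x, 0.5, type = 7)),
    p25 = unname(quantile(x, 0.25, type = 7)),
    p75 = unname(quantile(x, 0.75, type = 7)),
    max = max(x),
    variation1 = sum(abs(x[-1] - x[-n])^1),
    variation2 = sum(abs(x[-1] - x[-n])^2),
    variation3 = sum(abs(x[-1] - x[-n])^3))
}

# Independent partition of a raw series into grid windows: data.frame of
# per-interval magnitude vectors keyed by an independently computed bucket.
oracle_partition <- function(series, period_minutes, origin = T0) {
  d <- series$data
  mag <- sqrt(d$x^2 + d$y^2 + d$z^2)
  bucket <- as.integer(as.numeric(difftime(d$timestamp, origin, units = "mins")) %/%
                         period_minutes)
  split(mag, bucket)
}

# --- independent CUSUM loop -------------------------------------------------
oracle_cusum <- function(x, mu0, kappa) {
  cp <- 0
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (!is.na(x[i])) cp <- max(0, x[i] - (mu0 + kappa) + cp)
    out[i] <- cp
  }
  out
}

# --- independent day-offset baseline ---------------------------------------
oracle_baseline <- function(values, T_day, r, i) {
  vapply(i, function(ii) {
    lo <- ii - T_day - r + 1L   # 1-based positions for 0-based interval ii
    hi <- ii - T_day + r + 1L
    if (lo < 1L) return(NA_real_)
    w <- values[lo:hi]
    if (sum(!is.na(w)) < ceiling((2 * r + 1) / 2)) return(NA_real_)
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

# --- fixture builders -------------------------------------------------------
make_feature <- function(values, period = 60L, sow = "s1", ch = "variation1",
                         origin = T0) {
  feature_series(sow, ch, interval_grid(period, origin), values,
                 n_obs = rep(10L, length(values)))
}

# feature series repeating a daily profile for `days` days (24 h-periodic)
periodic_feature <- function(profile, days, period = 60L, ...) {
  T_day <- 1440L / period
  stopifnot(length(profile) == T_day)
  make_feature(rep(profile, days), period = period, ...)
}

# small raw series with prescribed magnitudes along the x axis
mags_series <- function(mags, start = T0, step = 1, sow = "s1") {
  accel_series(sow, data.frame(
    timestamp = start + (seq_along(mags) - 1) * step,
    x = mags, y = 0, z = 0))
}

# random raw series over `hours` hours at 1 Hz with i.i.d. dropout
random_series <- function(seed, hours = 3, dropout = 0.15, start = T0,
                          sow = "s1") {
  set.seed(seed)
  n <- as.integer(hours * 3600)
  keep <- runif(n) >= dropout
  ts <- (start + seq_len(n) - 1)[keep]
  m <- sum(keep)
  accel_series(sow, data.frame(timestamp = ts,
                               x = rnorm(m, 0, 0.3), y = rnorm(m, 0, 0.3),
                               z = 1 + rnorm(m, 0, 0.3)))
}

# A raw stream whose days are exact copies and whose windows are identical
# across clock slots: magnitude follows a 10-minute sine cycle, so every
# (possibly overlap-extended) grid window of any admissible period contains
# the same sample pattern. Starts `lead_seconds` before the grid origin so
# that extended windows at the left edge are fully covered.
slotflat_series <- function(days = 3, lead_seconds = 600, sow = "s1") {
  t0 <- as.numeric(T0) - lead_seconds
  n <- days * 86400 + 2 * lead_seconds
  ts <- t0 + seq_len(n) - 1
  m <- 1 + 0.2 * sin(2 * pi * (ts %% 600) / 600)
  accel_series(sow, data.frame(
    timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = UTC),
    x = m, y = 0, z = 0))
}

# index series with prescribed values on a 60-min grid anchored at T0
make_index <- function(values, period = 60L, index_type = "CumDi",
                       ma_range = 1L, sow = "s1", ch = "variation1") {
  f <- make_feature(rep(NA_real_, length(values)), period = period, sow = sow,
                    ch = ch)
  farrowcast:::index_series(f, index_type, ma_range, values)
}

# short default sow (housed 3 days before calculated date) for cheap tests
quick_scenario <- function(seed = 7, onset_offset_h = -10, lead_h = 22,
                           housed_days = 3, ...) {
  onset <- CF + onset_offset_h * 3600
  sow_scenario(paste0("q", seed), CF, onset, onset - lead_h * 3600,
               housed_at = CF - housed_days * 86400, seed = seed, ...)
}
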