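#' Scenario for one simulated sow
#'
#' Ground-truth description of a single sow used by [simulate_sow()]. Times
#' follow the farrowing-unit convention: sows are moved into the farrowing pen
#' seven days before the calculated (expected) farrowing date, the calculated
#' date is the midnight starting Day 0, and the true onset (birth of the first
#' piglet) is scattered around the calculated date. Nest-building raises
#' activity over the last half to one and a half days before onset.
#'
#' @param sow_id character identifier.
#' @param calculated_farrowing calculated farrowing date; coerced to the
#'   midnight (UTC) starting Day 0.
#' @param true_onset true onset of farrowing (birth of first piglet).
#' @param surge_start time at which the pre-farrowing activity surge begins;
#'   must lie before `true_onset`.
#' @param housed_at time the sow enters the pen; default seven days before the
#'   calculated date. Must lie before `true_onset`.
#' @param baseline_activity nocturnal activity-noise standard deviation in g
#'   (per accelerometer axis); must be >= 0.
#' @param circadian_amplitude daytime increase of the activity-noise s.d. as a
#'   fraction of baseline (>= 0); the diurnal profile is high roughly
#'   06:00-21:00 and low at night.
#' @param surge_multiplier factor (>= 1) by which the activity-noise s.d. is
#'   multiplied at the peak of the pre-farrowing surge (reached at onset).
#' @param dropout_rate probability in `[0, 1)` that an individual 1 Hz sample
#'   is lost before storage. The study system stored on average 74,619 of
#'   86,400 possible samples per day, i.e. about 13.6 % loss.
#' @param day_effect_sd step standard deviation (log scale) of a slow
#'   random-walk day-level activity multiplier, emulating gradual day-to-day
#'   drift of a sow's overall activity; 0 disables it. Consecutive days stay
#'   similar (which day-offset differencing exploits) while the level can
#'   wander over the housing week (which penalises monitoring the raw
#'   characteristic).
#' @param bout_sd stationary standard deviation (log scale) of an
#'   Ornstein-Uhlenbeck bout-intensity process multiplying the activity-noise
#'   s.d., emulating the bout structure of behaviour (resting vs rooting /
#'   pawing spells) that makes hourly fluctuation characteristics strongly
#'   variable from interval to interval; 0 disables it.
#' @param bout_tau_minutes correlation time of the bout process in minutes.
#' @param surge_shape `"quadratic"` (default): the surge multiplier ramps as
#'   `1 + (m - 1) * f^2` with `f` the elapsed fraction of
#'   `[surge_start, true_onset]`, capturing activity that intensifies towards
#'   parturition; `"linear"`: ramp linear in `f`; `"step"`: full multiplier
#'   from `surge_start` onwards.
#' @param seed integer seed making the sow's stream fully reproducible.
#' @return an object of class `sow_scenario`.
#' @export
sow_scenario <- function(sow_id,
                         calculated_farrowing,
                         true_onset,
                         surge_start,
                         housed_at = NULL,
                         baseline_activity = 0.04,
                         circadian_amplitude = 0.8,
                         surge_multiplier = 4,
                         dropout_rate = 0.136,
                         day_effect_sd = 0.1,
                         bout_sd = 0.35,
                         bout_tau_minutes = 45,
                         surge_shape = c("quadratic", "linear", "step"),
                         seed = 1L) {
  calculated_farrowing <- midnight_of(calculated_farrowing)
  true_onset <- as_utc(true_onset, "true_onset")
  surge_start <- as_utc(surge_start, "surge_start")
  housed_at <- if (is.null(housed_at)) calculated_farrowing - 7 * 86400
               else as_utc(housed_at, "housed_at")
  surge_shape <- match.arg(surge_shape)

  if (!is.character(sow_id) || length(sow_id) != 1L || !nzchar(sow_id))
    stop_invariant("sow_id", "sow_id must be a non-empty string")
  if (!(housed_at < true_onset))
    stop_invariant("housed_at < true_onset", "sow %s: housed at %s, onset %s",
                   sow_id, format_utc(housed_at), format_utc(true_onset))
  if (!(surge_start < true_onset))
    stop_invariant("surge_start < true_onset", "sow %s: surge %s, onset %s",
                   sow_id, format_utc(surge_start), format_utc(true_onset))
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop_invariant("dropout_rate in [0, 1)", "got %s", format(dropout_rate))
  if (!is.numeric(surge_multiplier) || surge_multiplier < 1)
    stop_invariant("surge_multiplier >= 1", "got %s", format(surge_multiplier))
  if (!is.numeric(baseline_activity) || baseline_activity < 0)
    stop_invariant("baseline_activity >= 0", "got %s", format(baseline_activity))
  if (!is.numeric(circadian_amplitude) || circadian_amplitude < 0)
    stop_invariant("circadian_amplitude >= 0", "got %s", format(circadian_amplitude))
  if (!is.numeric(day_effect_sd) || day_effect_sd < 0)
    stop_invariant("day_effect_sd >= 0", "got %s", format(day_effect_sd))
  if (!is.numeric(bout_sd) || bout_sd < 0)
    stop_invariant("bout_sd >= 0", "got %s", format(bout_sd))
  if (!is.numeric(bout_tau_minutes) || bout_tau_minutes <= 0)
    stop_invariant("bout_tau_minutes > 0", "got %s", format(bout_tau_minutes))

  structure(
    list(sow_id = sow_id, housed_at = housed_at,
         calculated_farrowing = calculated_farrowing, true_onset = true_onset,
         surge_start = surge_start, baseline_activity = baseline_activity,
         circadian_amplitude = circadian_amplitude,
         surge_multiplier = surge_multiplier, dropout_rate = dropout_rate,
         day_effect_sd = day_effect_sd, bout_sd = bout_sd,
         bout_tau_minutes = bout_tau_minutes, surge_shape = surge_shape,
         seed = as.integer(seed)),
    class = "sow_scenario")
}

#' @export
print.sow_scenario <- function(x, ...) {
  cat(sprintf(paste0("<sow_scenario> %s\n  housed %s, calculated %s\n",
                     "  onset %s, surge from %s (x%.2f, %s)\n",
                     "  baseline %.3f g, circadian x(1+%.2f), dropout %.3f, seed %d\n"),
              x$sow_id, format_utc(x$housed_at), format_utc(x$calculated_farrowing),
              format_utc(x$true_onset), format_utc(x$surge_start),
              x$surge_multiplier, x$surge_shape, x$baseline_activity,
              x$circadian_amplitude, x$dropout_rate, x$seed))
  invisible(x)
}

#' Diurnal activity profile
#'
#' Smoothed two-level day/night profile in `[0, 1]`: close to 1 between about
#' 06:00 and 21:00 and close to 0 at night, with logistic shoulders. This
#' plateau-like shape mirrors daily activity under regular husbandry rather
#' than a sinusoid.
#'
#' @param seconds_of_day numeric vector, seconds since local midnight.
#' @param day_start,day_end plateau limits in hours.
#' @param softness shoulder width in hours.
#' @return numeric vector in `[0, 1]`.
#' @export
circadian_profile <- function(seconds_of_day, day_start = 6, day_end = 21,
                              softness = 0.75) {
  h <- (seconds_of_day / 3600) %% 24
  plogis((h - day_start) / softness) * plogis((day_end - h) / softness)
}

surge_factor <- function(t_num, scenario) {
  on <- as.numeric(scenario$true_onset)
  s0 <- as.numeric(scenario$surge_start)
  f <- pmin(pmax((t_num - s0) / max(on - s0, 1), 0), 1)
  m <- scenario$surge_multiplier
  ramp <- switch(scenario$surge_shape,
                 quadratic = f^2,
                 linear = f,
                 step = as.numeric(f > 0))
  1 + (m - 1) * ramp
}

#' Simulate one sow's accelerometer stream
#'
#' Generates a 1 Hz triaxial stream from housing to 12 h after the true onset.
#' The signal is a unit gravity vector with slowly drifting orientation
#' (random-walk angles interpolated from one-minute knots) plus zero-mean
#' Gaussian activity noise per axis whose standard deviation follows
#' `baseline_activity * (1 + circadian_amplitude * c(t))`, modulated by a
#' slow day-level random walk, a lognormal Ornstein-Uhlenbeck bout-intensity
#' process, and the pre-farrowing surge ramp (see [sow_scenario()]). Each
#' sample is independently dropped with probability `dropout_rate`. The
#' output is fully deterministic given the scenario seed.
#'
#' @param scenario a [sow_scenario()].
#' @return an object of class `accel_series`: a list with `sow_id` and `data`,
#'   a `data.table` with columns `timestamp` (POSIXct UTC, whole seconds,
#'   strictly increasing), `x`, `y`, `z` (g).
#' @export
simulate_sow <- function(scenario) {
  if (!inherits(scenario, "sow_scenario"))
    stop("scenario must be a sow_scenario", call. = FALSE)
  t0 <- floor(as.numeric(scenario$housed_at))
  t1 <- floor(as.numeric(scenario$true_onset) + 12 * 3600)
  n <- as.integer(t1 - t0)
  origin <- as.numeric(midnight_of(scenario$housed_at))

  local_seed(scenario$seed, {
    keep <- runif(n) >= scenario$dropout_rate
    n_days <- as.integer(ceiling((t1 - origin) / 86400))
    # slow day-level drift: random walk in log activity level
    day_mult <- if (scenario$day_effect_sd > 0) {
      exp(cumsum(rnorm(n_days, 0, scenario$day_effect_sd)))
    } else rep(1, n_days)

    # orientation random walk on 60 s knots, linearly interpolated
    knots <- seq(t0, t1 + 60, by = 60)
    incl <- runif(1, 0.2, 0.8) * pi +
      cumsum(rnorm(length(knots), 0, 0.02))
    azim <- runif(1, 0, 2) * pi +
      cumsum(rnorm(length(knots), 0, 0.03))

    # bout-intensity modulation: lognormal OU on the same knots
    bout <- if (scenario$bout_sd > 0) {
      phi <- exp(-1 / scenario$bout_tau_minutes)   # knot spacing is 1 min
      eps <- rnorm(length(knots), 0, scenario$bout_sd * sqrt(1 - phi^2))
      z <- numeric(length(knots))
      z[1] <- rnorm(1, 0, scenario$bout_sd)
      for (j in 2:length(knots)) z[j] <- phi * z[j - 1] + eps[j]
      exp(z - scenario$bout_sd^2 / 2)
    } else rep(1, length(knots))

    ts <- (t0 + seq_len(n) - 1)[keep]
    m <- length(ts)
    gi <- approx(knots, incl, xout = ts)$y
    ga <- approx(knots, azim, xout = ts)$y
    gx <- sin(gi) * cos(ga); gy <- sin(gi) * sin(ga); gz <- cos(gi)
    bt <- approx(knots, bout, xout = ts)$y

    tod <- (ts - origin) %% 86400
    didx <- as.integer(floor((ts - origin) / 86400)) + 1L
    sigma <- scenario$baseline_activity *
      (1 + scenario$circadian_amplitude * circadian_profile(tod)) *
      day_mult[didx] * bt * surge_factor(ts, scenario)

    dt <- data.table(
      timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
      x = gx + rnorm(m) * sigma,
      y = gy + rnorm(m) * sigma,
      z = gz + rnorm(m) * sigma)
    accel_series(scenario$sow_id, dt)
  })
}

#' Construct an acceleration series
#'
#' @param sow_id character identifier.
#' @param data data.frame/data.table with columns `timestamp` (POSIXct),
#'   `x`, `y`, `z` in g. Timestamps must be strictly increasing and all values
#'   finite.
#' @return an object of class `accel_series`.
#' @export
accel_series <- function(sow_id, data) {
  data <- as.data.table(data)
  req <- c("timestamp", "x", "y", "z")
  if (!all(req %in% names(data)))
    stop("accel data needs columns timestamp, x, y, z", call. = FALSE)
  data <- data[, req, with = FALSE]
  data[, timestamp := as_utc(timestamp)]
  if (nrow(data) > 1L) {
    dts <- diff(as.numeric(data$timestamp))
    if (any(dts <= 0))
      stop_invariant("timestamps strictly increasing",
                     "sow %s: violation at row %d", sow_id,
                     which(dts <= 0)[1L] + 1L)
  }
  if (nrow(data) && !all(is.finite(data$x) & is.finite(data$y) & is.finite(data$z)))
    stop_invariant("finite values only", "sow %s has non-finite samples", sow_id)
  structure(list(sow_id = sow_id, data = data), class = "accel_series")
}

#' @export
print.accel_series <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<accel_series> sow %s, %d samples", x$sow_id, n))
  if (n) cat(sprintf(" [%s .. %s]", format_utc(x$data$timestamp[1L]),
                     format_utc(x$data$timestamp[n])))
  cat("\n")
  invisible(x)
}

#' Configuration for a synthetic cohort
#'
#' Per-sow parameters are drawn independently from uniform ranges; true onsets
#' are scattered around the shared calculated farrowing date and the activity
#' surge begins 12-36 h before the individual onset by default, reflecting
#' nest-building that typically starts within the last day or so before
#' farrowing, with some sows farrowing days before the calculated date.
#'
#' @param n_sows number of sows (>= 1).
#' @param seed master seed; per-sow seeds are derived reproducibly.
#' @param calculated_farrowing shared calculated farrowing date (midnight UTC).
#' @param onset_offset_days range (days, relative to the calculated date) of
#'   the uniform true-onset offset; default `c(-2.5, 1)`.
#' @param surge_lead_hours range (hours before onset) of the uniform surge
#'   lead; default `c(12, 36)`.
#' @param baseline_activity_range,circadian_amplitude_range,surge_multiplier_range
#'   uniform ranges for the per-sow scenario parameters.
#' @param dropout_rate shared sample-loss probability; default 0.136.
#' @param day_effect_sd shared day-level random-walk step s.d.; default 0.1.
#' @param bout_sd,bout_tau_minutes shared bout-process scale and correlation
#'   time (see [sow_scenario()]).
#' @param surge_shape surge ramp shape passed to [sow_scenario()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_sows,
                          seed = 1L,
                          calculated_farrowing = "2014-01-15",
                          onset_offset_days = c(-2.5, 1),
                          surge_lead_hours = c(12, 36),
                          baseline_activity_range = c(0.02, 0.06),
                          circadian_amplitude_range = c(0.6, 1.2),
                          surge_multiplier_range = c(3, 5),
                          dropout_rate = 0.136,
                          day_effect_sd = 0.1,
                          bout_sd = 0.35,
                          bout_tau_minutes = 45,
                          surge_shape = "quadratic") {
  if (!is.numeric(n_sows) || length(n_sows) != 1L || n_sows < 1)
    stop_invariant("n_sows >= 1", "got %s", format(n_sows))
  rng2 <- function(x, nm) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || x[1L] > x[2L])
      stop(sprintf("%s must be a (lo, hi) range", nm), call. = FALSE)
    x
  }
  onset_offset_days <- rng2(onset_offset_days, "onset_offset_days")
  # housing is Day -7; the parameterization days need a prior day of data, so
  # onsets must stay at least 2 days after housing
  if (onset_offset_days[1L] < -5)
    stop_invariant("true_onset >= housed_at + 2 days",
                   "onset offset %.2f d puts onset < 2 d after housing",
                   onset_offset_days[1L])
  structure(
    list(n_sows = as.integer(n_sows), seed = as.integer(seed),
         calculated_farrowing = midnight_of(calculated_farrowing),
         onset_offset_days = onset_offset_days,
         surge_lead_hours = rng2(surge_lead_hours, "surge_lead_hours"),
         baseline_activity_range = rng2(baseline_activity_range, "baseline_activity_range"),
         circadian_amplitude_range = rng2(circadian_amplitude_range, "circadian_amplitude_range"),
         surge_multiplier_range = rng2(surge_multiplier_range, "surge_multiplier_range"),
         dropout_rate = dropout_rate, day_effect_sd = day_effect_sd,
         bout_sd = bout_sd, bout_tau_minutes = bout_tau_minutes,
         surge_shape = surge_shape),
    class = "cohort_config")
}

runif_rng <- function(n, range) runif(n, range[1L], range[2L])

#' Draw the ground-truth scenarios of a cohort
#'
#' Deterministic given `config$seed`; [simulate_cohort()] uses these scenarios.
#'
#' @param config a [cohort_config()].
#' @return list of [sow_scenario()] objects.
#' @export
draw_cohort_scenarios <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_sows
  cf <- config$calculated_farrowing
  local_seed(config$seed, {
    offs <- runif_rng(n, config$onset_offset_days)
    leads <- runif_rng(n, config$surge_lead_hours)
    base <- runif_rng(n, config$baseline_activity_range)
    amp <- runif_rng(n, config$circadian_amplitude_range)
    mult <- runif_rng(n, config$surge_multiplier_range)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      # whole-second event times, matching the 1 Hz sampling resolution
      onset <- cf + round(offs[i] * 86400)
      sow_scenario(sow_id = sprintf("sow%02d", i),
                   calculated_farrowing = cf,
                   true_onset = onset,
                   surge_start = onset - round(leads[i] * 3600),
                   baseline_activity = base[i],
                   circadian_amplitude = amp[i],
                   surge_multiplier = mult[i],
                   dropout_rate = config$dropout_rate,
                   day_effect_sd = config$day_effect_sd,
                   bout_sd = config$bout_sd,
                   bout_tau_minutes = config$bout_tau_minutes,
                   surge_shape = config$surge_shape,
                   seed = seeds[i])
    })
  })
}

#' Simulate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return an object of class `sow_cohort`: a list of entries
#'   `list(scenario = sow_scenario, series = accel_series)`.
#' @seealso [cohort_manifest()] for the ground-truth table.
#' @export
simulate_cohort <- function(config) {
  scens <- draw_cohort_scenarios(config)
  out <- lapply(scens, function(sc) list(scenario = sc, series = simulate_sow(sc)))
  structure(out, class = "sow_cohort", config = config)
}

#' Ground-truth manifest of a cohort
#'
#' @param cohort a `sow_cohort` (from [simulate_cohort()]) or a list of
#'   [sow_scenario()] objects.
#' @return data.table with one row per sow: identifiers, housing/calculated/
#'   onset/surge times and generator parameters.
#' @export
cohort_manifest <- function(cohort) {
  scens <- lapply(cohort, function(e) if (inherits(e, "sow_scenario")) e else e$scenario)
  rbindlist(lapply(scens, function(s) data.table(
    sow_id = s$sow_id,
    housed_at = s$housed_at,
    calculated_farrowing = s$calculated_farrowing,
    true_onset = s$true_onset,
    surge_start = s$surge_start,
    baseline_activity = s$baseline_activity,
    circadian_amplitude = s$circadian_amplitude,
    surge_multiplier = s$surge_multiplier,
    dropout_rate = s$dropout_rate,
    day_effect_sd = s$day_effect_sd,
    bout_sd = s$bout_sd,
    bout_tau_minutes = s$bout_tau_minutes,
    surge_shape = s$surge_shape,
    seed = s$seed)))
}

#' Rebuild scenarios from a manifest table
#'
#' Inverse of [cohort_manifest()]; used when ground truth is read back from a
#' manifest CSV.
#'
#' @param manifest data.table as returned by [cohort_manifest()] or
#'   [read_manifest_csv()].
#' @return list of [sow_scenario()] objects.
#' @export
scenarios_from_manifest <- function(manifest) {
  manifest <- as.data.table(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i]
    sow_scenario(sow_id = r$sow_id,
                 calculated_farrowing = r$calculated_farrowing,
                 true_onset = r$true_onset, surge_start = r$surge_start,
                 housed_at = r$housed_at,
                 baseline_activity = r$baseline_activity,
                 circadian_amplitude = r$circadian_amplitude,
                 surge_multiplier = r$surge_multiplier,
                 dropout_rate = r$dropout_rate,
                 day_effect_sd = r$day_effect_sd,
                 bout_sd = r$bout_sd,
                 bout_tau_minutes = r$bout_tau_minutes,
                 surge_shape = r$surge_shape, seed = r$seed)
  })
}

#' Pair scenarios with sample series into a cohort
#'
#' @param scenarios list of [sow_scenario()].
#' @param series named list of `accel_series` (names = sow ids), e.g. from
#'   [read_accel_csv()].
#' @return a `sow_cohort`.
#' @export
as_sow_cohort <- function(scenarios, series) {
  out <- lapply(scenarios, function(sc) {
    s <- series[[sc$sow_id]]
    if (is.null(s)) stop(sprintf("no samples for sow %s", sc$sow_id), call. = FALSE)
    list(scenario = sc, series = s)
  })
  structure(out, class = "sow_cohort")
}

#' @export
print.sow_cohort <- function(x, ...) {
  cat(sprintf("<sow_cohort> %d sows\n", length(x)))
  invisible(x)
}
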