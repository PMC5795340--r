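#' Cohort-level evaluation of the CUSUM detector
#'
#' Detection rates within fixed pre-onset windows (12 and 48 h by default),
#' cumulative detection curves over the prediction period, and the full
#' factor-grid search over distribution characteristics, acceleration
#' indices, window lengths, moving-average ranges, allowance (k) and
#' smoothing (h) values, and parameterization scenarios.
#'
#' @name evaluate
NULL

#' Detection rate within a pre-onset window
#'
#' A sow counts as detected within `window_hours` iff its first-alarm offset
#' lies in `[-window_hours, 0]` hours (closed window). Sows without an alarm,
#' or whose first alarm came earlier than the window, count in the
#' denominator only.
#'
#' @param offsets numeric vector of per-sow first-alarm offsets in hours
#'   (negative = before onset), `NA` = no alarm.
#' @param window_hours positive window length in hours.
#' @return percentage in `[0, 100]`.
#' @export
detection_rate <- function(offsets, window_hours) {
  if (length(offsets) == 0L) stop("empty cohort", call. = FALSE)
  if (!is.numeric(window_hours) || window_hours <= 0)
    stop("window_hours must be positive", call. = FALSE)
  100 * mean(!is.na(offsets) & offsets >= -window_hours & offsets <= 0)
}

#' Cumulative detection curve
#'
#' For each allowance value `k`, the non-decreasing step function of the
#' cumulative percentage of sows detected by a given hour before onset
#' (`hours_before_onset` runs from the start of the prediction period towards
#' 0).
#'
#' @param offsets data.frame with columns `k` and `offset_hours` (one row per
#'   sow and k; `NA` offset = no alarm).
#' @param k_values optional subset of k values to tabulate.
#' @param hours evaluation grid of hours before onset (non-positive).
#' @return data.table with columns `k`, `hours_before_onset`, `cum_pct`.
#' @export
cumulative_detection_curve <- function(offsets, k_values = NULL,
                                       hours = seq(-96, 0, by = 1)) {
  offsets <- as.data.table(offsets)
  stopifnot(all(c("k", "offset_hours") %in% names(offsets)))
  if (!is.null(k_values)) offsets <- offsets[k %in% k_values]
  if (nrow(offsets) == 0L) stop("empty cohort", call. = FALSE)
  offsets[, {
    off <- offset_hours
    list(hours_before_onset = hours,
         cum_pct = vapply(hours, function(t) 100 * mean(!is.na(off) & off <= t),
                          numeric(1)))
  }, keyby = k]
}

#' Evaluation configuration
#'
#' Defaults reproduce the full factor enumeration: the five fluctuation
#' characteristics, all seven indices, 10/30/60 min windows, the
#' period-admissible moving-average ranges, the full k and h grids and all
#' three parameterization scenarios.
#'
#' @param windows_hours detection windows in hours (default `c(12, 48)`).
#' @param characteristics characteristics to evaluate.
#' @param index_types indices to evaluate (see [index_types()]).
#' @param periods window lengths in minutes.
#' @param ma_ranges named list (by period) of half-widths, or `NULL` for all
#'   admissible values.
#' @param k_values allowance grid (default [cusum_k_grid()]).
#' @param h_values smoothing grid (default [cusum_h_grid()]).
#' @param scenarios parameterization scenarios (default m4, m5, m45).
#' @param k_mode `"standardized"` or `"raw"` (see [fit_cusum_params()]).
#' @param min_obs per-interval minimum sample count.
#' @return an object of class `evaluation_config`.
#' @export
evaluation_config <- function(windows_hours = c(12, 48),
                              characteristics = fluctuation_characteristics(),
                              index_types = farrowcast::index_types(),
                              periods = c(10L, 30L, 60L),
                              ma_ranges = NULL,
                              k_values = cusum_k_grid(),
                              h_values = cusum_h_grid(),
                              scenarios = c("m4", "m5", "m45"),
                              k_mode = c("standardized", "raw"),
                              min_obs = 2L) {
  if (any(windows_hours <= 0)) stop("windows must be positive", call. = FALSE)
  characteristics <- match.arg(characteristics, ALL_CHARACTERISTICS, several.ok = TRUE)
  index_types <- match.arg(index_types, INDEX_TYPES, several.ok = TRUE)
  stopifnot(all(periods %in% c(10L, 30L, 60L)))
  if (is.null(ma_ranges)) {
    ma_ranges <- lapply(as.character(periods), ma_ranges_for)
    names(ma_ranges) <- as.character(periods)
  } else {
    for (p in as.character(periods))
      if (!all(ma_ranges[[p]] %in% ma_ranges_for(p)))
        stop(sprintf("inadmissible ma_range for %s min", p), call. = FALSE)
  }
  scenarios <- match.arg(scenarios, PARAM_SCENARIOS, several.ok = TRUE)
  structure(list(windows_hours = sort(windows_hours),
                 characteristics = characteristics, index_types = index_types,
                 periods = as.integer(periods), ma_ranges = ma_ranges,
                 k_values = k_values, h_values = h_values,
                 scenarios = scenarios, k_mode = match.arg(k_mode),
                 min_obs = as.integer(min_obs)),
            class = "evaluation_config")
}

# All (index_type, ma_range) cells for one period. Orig and CumAv carry no
# moving-average range.
index_cells_for <- function(config, period) {
  cells <- list()
  for (it in config$index_types) {
    if (it %in% BASELINE_INDEX_TYPES) {
      for (r in config$ma_ranges[[as.character(period)]])
        cells[[length(cells) + 1L]] <- list(index_type = it, ma_range = as.integer(r))
    } else {
      cells[[length(cells) + 1L]] <- list(index_type = it, ma_range = NA_integer_)
    }
  }
  cells
}

# First-alarm offsets of one sow for one index series across the k x h grid.
# The trajectory depends on k only; for each h the alarm is the first strict
# exceedance of sigma * h.
sow_cell_offsets <- function(index, scenario, config, cf, true_onset) {
  fit <- tryCatch(
    fit_cusum_params(index, cf, scenario = scenario, k = 1, h = 4,
                     k_mode = config$k_mode),
    error = function(e) NULL)
  nk <- length(config$k_values); nh <- length(config$h_values)
  if (is.null(fit)) {
    return(data.table(k = rep(config$k_values, each = nh),
                      h = rep(config$h_values, nk),
                      offset_hours = NA_real_, evaluable = FALSE))
  }
  start <- cf - 3 * 86400
  n_all <- length(index$values)
  starts <- as.numeric(interval_start(index$grid, seq_len(n_all) - 1L))
  sel <- which(starts >= as.numeric(start) & starts < as.numeric(true_onset))
  x <- index$values[sel]
  t_sel <- starts[sel]
  onset_num <- as.numeric(true_onset)
  rows <- vector("list", nk)
  for (ki in seq_len(nk)) {
    k <- config$k_values[ki]
    kappa <- if (config$k_mode == "standardized") k * fit$sigma else k
    traj <- cusum_recursion(x, fit$mu0 + kappa)
    offs <- vapply(config$h_values, function(h) {
      i <- which(traj > fit$sigma * h)
      if (length(i)) (t_sel[i[1L]] - onset_num) / 3600 else NA_real_
    }, numeric(1))
    rows[[ki]] <- data.table(k = k, h = config$h_values, offset_hours = offs,
                             evaluable = TRUE)
  }
  rbindlist(rows)
}

#' Factor-grid search over a cohort
#'
#' Runs the complete pipeline (features -> indices -> sow-individual CUSUM)
#' for every factor-grid cell of `config` on every sow and tabulates per-cell
#' detection rates. Sows whose index series has no defined value inside a
#' cell's parameterization period cannot be parameterized; they are excluded
#' from that cell's denominator and reported via `n_excluded`.
#'
#' @param cohort a `sow_cohort` from [simulate_cohort()], or a list of
#'   `list(scenario = sow_scenario, series = accel_series)` entries.
#' @param config an [evaluation_config()].
#' @param verbose print per-sow progress.
#' @return an object of class `cohort_evaluation` with elements:
#'   `cells` (one row per cell x window: detection counts and rates),
#'   `best` (per characteristic x index x period x scenario x window, the
#'   maximum rate over ma_range, k and h, with the arg-max),
#'   `offsets` (per-sow first-alarm offsets for every cell) and `config`.
#' @export
grid_search <- function(cohort, config = evaluation_config(), verbose = FALSE) {
  stopifnot(inherits(config, "evaluation_config"))
  all_offsets <- list()
  for (entry in cohort) {
    sc <- entry$scenario; series <- entry$series
    if (verbose) message("grid_search: sow ", sc$sow_id)
    cf <- sc$calculated_farrowing
    for (period in config$periods) {
      grid <- interval_grid(period, sc$housed_at)
      feats <- compute_features(series, grid, config$characteristics,
                                min_obs = config$min_obs)
      cells <- index_cells_for(config, period)
      need_over <- any(vapply(cells, function(cl) cl$index_type == "Over", logical(1)))
      for (ch in config$characteristics) {
        f <- feats[[ch]]
        over_feature <- NULL
        if (need_over) {
          ext <- extended_feature_values(series, ch, grid, overlap_for(period),
                                         config$min_obs)
          over_feature <- feature_series(series$sow_id, ch, grid, ext$values,
                                         ext$n_obs)
        }
        for (cl in cells) {
          idx <- if (cl$index_type == "Over") {
            o <- quot_index(over_feature, cl$ma_range)
            o$index_type <- "Over"
            o
          } else {
            compute_index(f, cl$index_type, cl$ma_range)
          }
          for (scen in config$scenarios) {
            offs <- sow_cell_offsets(idx, scen, config, cf, sc$true_onset)
            offs[, `:=`(sow_id = sc$sow_id, characteristic = ch,
                        index_type = cl$index_type, period = period,
                        ma_range = cl$ma_range, scenario = scen)]
            all_offsets[[length(all_offsets) + 1L]] <- offs
          }
        }
      }
    }
  }
  offsets <- rbindlist(all_offsets)
  setcolorder(offsets, c("sow_id", "characteristic", "index_type", "period",
                         "ma_range", "scenario", "k", "h", "offset_hours",
                         "evaluable"))
  cells <- rbindlist(lapply(config$windows_hours, function(w) {
    out <- offsets[, {
      ev <- evaluable
      det <- ev & !is.na(offset_hours) & offset_hours >= -w & offset_hours <= 0
      list(window_hours = w, n_evaluable = sum(ev), n_excluded = sum(!ev),
           n_detected = sum(det),
           detection_rate = if (sum(ev)) 100 * sum(det) / sum(ev) else NA_real_)
    }, keyby = list(characteristic, index_type, period, ma_range, scenario, k, h)]
    out
  }))
  best <- cells[!is.na(detection_rate),
                .SD[which.max(detection_rate)],
                keyby = list(characteristic, index_type, period, scenario,
                             window_hours)]
  setnames(best, c("ma_range", "k", "h"), c("best_ma_range", "best_k", "best_h"))
  structure(list(cells = cells, best = best, offsets = offsets, config = config),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d cells x windows, %d best-cell rows\n",
              nrow(x$cells), nrow(x$best)))
  print(x$best[, list(characteristic, index_type, period, scenario,
                      window_hours, detection_rate)], nrows = 20L)
  invisible(x)
}

#' Best detection rate of one factor cell
#'
#' Convenience accessor: maximum detection rate over the k and h grids (and
#' the arg-max) for one characteristic x index x period x scenario cell and
#' one window, optionally at a fixed moving-average range.
#'
#' @param evaluation a `cohort_evaluation`.
#' @param characteristic,index_type,period,scenario cell coordinates.
#' @param window_hours detection window.
#' @param ma_range optional fixed half-width.
#' @return one-row data.table (rate and arg-max), or zero rows if absent.
#' @export
best_cell <- function(evaluation, characteristic, index_type, period, scenario,
                      window_hours, ma_range = NULL) {
  ch <- characteristic; it <- index_type; p <- period; sc <- scenario
  w <- window_hours
  cells <- evaluation$cells[characteristic == ch & index_type == it &
                              period == p & scenario == sc & window_hours == w]
  if (!is.null(ma_range)) {
    r <- ma_range
    cells <- cells[ma_range %in% r]
  }
  cells <- cells[!is.na(detection_rate)]
  if (nrow(cells) == 0L) return(cells)
  cells[which.max(detection_rate)]
}
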