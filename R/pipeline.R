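#' Pipeline configuration
#'
#' Fully-resolved configuration for [run_pipeline()]. Every defaulted field is
#' serialised back out with the run manifest, so a run is reproducible from
#' its artifacts alone.
#'
#' @param cohort named list of [cohort_config()] arguments (at least
#'   `n_sows`).
#' @param evaluation named list of [evaluation_config()] arguments.
#' @param detect named list selecting the cell written out as per-sow chart
#'   CSVs: `characteristic`, `index_type`, `period`, `ma_range`, `k`, `h`,
#'   `scenario`, `k_mode`.
#' @param seed global seed (overrides `cohort$seed`).
#' @param curve_k k values tabulated in the cumulative-detection-curve CSV.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(n_sows = 20L),
                            evaluation = list(),
                            detect = list(characteristic = "variation1",
                                          index_type = "CumDi", period = 60L,
                                          ma_range = 1L, k = 5, h = 4,
                                          scenario = "m4",
                                          k_mode = "standardized"),
                            seed = 1L,
                            curve_k = c(1, 5, 15, 30)) {
  cohort$seed <- as.integer(seed)
  cc <- do.call(cohort_config, cohort)
  ec <- do.call(evaluation_config, evaluation)
  if (!detect$index_type %in% INDEX_TYPES)
    stop(sprintf("unknown index type '%s'", detect$index_type), call. = FALSE)
  if (detect$index_type %in% BASELINE_INDEX_TYPES)
    assert_ma_range(detect$period, detect$ma_range)
  structure(list(cohort = cc, evaluation = ec, detect = detect,
                 seed = as.integer(seed), curve_k = curve_k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#'
#' @param path YAML file with (optional) sections `cohort`, `evaluation`,
#'   `detect`, `seed`, `curve_k`.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "evaluation", "detect", "seed", "curve_k")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  defaults <- list(cohort = list(n_sows = 20L), evaluation = list(),
                   detect = list(characteristic = "variation1",
                                 index_type = "CumDi", period = 60L,
                                 ma_range = 1L, k = 5, h = 4, scenario = "m4",
                                 k_mode = "standardized"),
                   seed = 1L, curve_k = c(1, 5, 15, 30))
  merged <- defaults
  for (nm in names(raw)) {
    merged[[nm]] <- if (is.list(defaults[[nm]]) && is.list(raw[[nm]]))
      utils::modifyList(defaults[[nm]], raw[[nm]]) else raw[[nm]]
  }
  do.call(pipeline_config, merged)
}

serialize_config <- function(config) {
  cc <- config$cohort; ec <- config$evaluation
  list(seed = config$seed,
       cohort = list(n_sows = cc$n_sows, seed = cc$seed,
                     calculated_farrowing = format_utc(cc$calculated_farrowing),
                     onset_offset_days = cc$onset_offset_days,
                     surge_lead_hours = cc$surge_lead_hours,
                     baseline_activity_range = cc$baseline_activity_range,
                     circadian_amplitude_range = cc$circadian_amplitude_range,
                     surge_multiplier_range = cc$surge_multiplier_range,
                     dropout_rate = cc$dropout_rate,
                     day_effect_sd = cc$day_effect_sd,
                     bout_sd = cc$bout_sd,
                     bout_tau_minutes = cc$bout_tau_minutes,
                     surge_shape = cc$surge_shape),
       evaluation = list(windows_hours = ec$windows_hours,
                         characteristics = ec$characteristics,
                         index_types = ec$index_types, periods = ec$periods,
                         ma_ranges = ec$ma_ranges, k_values = ec$k_values,
                         h_values = ec$h_values, scenarios = ec$scenarios,
                         k_mode = ec$k_mode, min_obs = ec$min_obs),
       detect = config$detect, curve_k = config$curve_k)
}

#' Run the full pipeline
#'
#' Executes simulate -> features -> indices -> detect -> evaluate, writing
#' every intermediate artifact plus a machine-readable run manifest (resolved
#' configuration, seed, package version, per-file MD5 checksums) into
#' `out_dir`. Deterministic: the same configuration produces byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return invisibly, a named list of artifact paths plus the
#'   `cohort_evaluation`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  say <- function(...) if (verbose) message(...)

  say("stage simulate")
  cohort <- simulate_cohort(config$cohort)
  paths$accel <- file.path(out_dir, "samples.csv")
  write_accel_csv(cohort, paths$accel)
  paths$manifest <- file.path(out_dir, "manifest.csv")
  write_manifest_csv(cohort, paths$manifest)

  ec <- config$evaluation
  say("stage features")
  feats_by_sow <- list()
  for (entry in cohort) {
    sid <- entry$scenario$sow_id
    feats_by_sow[[sid]] <- lapply(ec$periods, function(p)
      compute_features(entry$series, interval_grid(p, entry$scenario$housed_at),
                       ec$characteristics, min_obs = ec$min_obs))
    names(feats_by_sow[[sid]]) <- as.character(ec$periods)
  }
  paths$features <- file.path(out_dir, "features.csv")
  write_feature_csv(feats_by_sow, paths$features)

  say("stage indices")
  idx_list <- list()
  for (entry in cohort) {
    sid <- entry$scenario$sow_id
    for (p in as.character(ec$periods)) {
      for (ch in ec$characteristics) {
        f <- feats_by_sow[[sid]][[p]][[ch]]
        for (cl in index_cells_for(ec, as.integer(p))) {
          idx_list[[length(idx_list) + 1L]] <-
            if (cl$index_type == "Over")
              over_index(entry$series, ch, f$grid, cl$ma_range, min_obs = ec$min_obs)
            else compute_index(f, cl$index_type, cl$ma_range)
        }
      }
    }
  }
  paths$indices <- file.path(out_dir, "indices.csv")
  write_index_csv(idx_list, paths$indices)

  say("stage detect")
  det <- config$detect
  alarm_rows <- list()
  dir.create(file.path(out_dir, "charts"), showWarnings = FALSE)
  for (entry in cohort) {
    sc <- entry$scenario
    grid <- interval_grid(det$period, sc$housed_at)
    f <- feats_by_sow[[sc$sow_id]][[as.character(det$period)]][[det$characteristic]]
    idx <- if (det$index_type == "Over")
      over_index(entry$series, det$characteristic, grid, det$ma_range,
                 min_obs = ec$min_obs)
    else compute_index(f, det$index_type, det$ma_range)
    res <- tryCatch({
      pars <- fit_cusum_params(idx, sc$calculated_farrowing, det$scenario,
                               k = det$k, h = det$h, k_mode = det$k_mode)
      run_cusum(idx, pars, end = sc$true_onset)
    }, error = function(e) NULL)
    chart_path <- file.path(out_dir, "charts", paste0(sc$sow_id, ".csv"))
    if (!is.null(res)) {
      write_cusum_csv(res, chart_path)
      off <- first_alarm_offset(res, sc$true_onset)
      alarm_rows[[length(alarm_rows) + 1L]] <- data.table(
        sow_id = sc$sow_id,
        first_alarm_time = if (is.na(res$first_alarm)) "" else
          format_utc(interval_start(res$grid, res$first_alarm)),
        offset_hours = num17(off), k = det$k, h = det$h, k_mode = det$k_mode,
        scenario = det$scenario, index_type = det$index_type,
        characteristic = det$characteristic, period = det$period,
        ma_range = det$ma_range, evaluable = TRUE)
    } else {
      alarm_rows[[length(alarm_rows) + 1L]] <- data.table(
        sow_id = sc$sow_id, first_alarm_time = "", offset_hours = "",
        k = det$k, h = det$h, k_mode = det$k_mode, scenario = det$scenario,
        index_type = det$index_type, characteristic = det$characteristic,
        period = det$period, ma_range = det$ma_range, evaluable = FALSE)
    }
  }
  paths$alarms <- file.path(out_dir, "alarms.csv")
  fwrite_chr(rbindlist(alarm_rows), paths$alarms)

  say("stage evaluate")
  ev <- grid_search(cohort, ec, verbose = verbose)
  paths$grid_cells <- file.path(out_dir, "grid_cells.csv")
  cells <- copy(ev$cells)[, detection_rate := num17(detection_rate)]
  fwrite_chr(cells, paths$grid_cells)
  paths$best <- file.path(out_dir, "best_summary.csv")
  best <- copy(ev$best)[, detection_rate := num17(detection_rate)]
  fwrite_chr(best, paths$best)
  paths$offsets <- file.path(out_dir, "offsets.csv")
  offs <- copy(ev$offsets)[, offset_hours := num17(offset_hours)]
  fwrite_chr(offs, paths$offsets)

  curve_src <- ev$offsets[
    characteristic == det$characteristic & index_type == det$index_type &
      period == det$period & scenario == det$scenario &
      (is.na(det$ma_range) | ma_range %in% det$ma_range) & h == det$h &
      evaluable == TRUE]
  paths$curve <- file.path(out_dir, "cumulative_curve.csv")
  if (nrow(curve_src)) {
    curve <- cumulative_detection_curve(curve_src, k_values = config$curve_k)
    curve[, cum_pct := num17(cum_pct)]
    fwrite_chr(curve, paths$curve)
  } else {
    fwrite_chr(data.table(k = numeric(0), hours_before_onset = numeric(0),
                          cum_pct = character(0)), paths$curve)
  }

  say("stage manifest")
  files <- unlist(paths)
  manifest <- list(package = "farrowcast",
                   version = as.character(packageVersion("farrowcast")),
                   seed = config$seed,
                   config = serialize_config(config),
                   artifacts = as.list(tools::md5sum(files)))
  paths$run_manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(evaluation = ev)))
}
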