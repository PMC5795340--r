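#' CSV interchange formats
#'
#' All files are plain CSV with ISO-8601 UTC timestamps. Numeric values are
#' serialised with 17 significant digits so that write -> read -> write is a
#' lossless, byte-identical round trip.
#'
#' Formats:
#' * samples: `sow_id,timestamp,x,y,z`
#' * cohort manifest: one row per sow with ground truth and parameters
#' * features (long): `sow_id,interval_start,period_minutes,characteristic,value,n_obs`
#' * indices (long): adds `index_type,ma_range`
#' * charts: `sow_id,interval_start,x,cusum,control_limit,alarm`
#'
#' @name io-formats
NULL

num17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

fwrite_chr <- function(dt, path) {
  fwrite(dt, path, quote = FALSE, na = "")
  invisible(path)
}

stop_row <- function(path, row, what) {
  # +1 accounts for the header line
  stop(sprintf("%s: line %d: %s", path, row + 1L, what), call. = FALSE)
}

#' Write acceleration samples to CSV
#'
#' @param x an `accel_series`, a `sow_cohort`, or a list of `accel_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(x, path) {
  if (inherits(x, "accel_series")) x <- list(x)
  series <- lapply(x, function(e) if (inherits(e, "accel_series")) e else e$series)
  dt <- rbindlist(lapply(series, function(s)
    data.table(sow_id = s$sow_id, timestamp = format_utc(s$data$timestamp),
               x = num17(s$data$x), y = num17(s$data$y), z = num17(s$data$z))))
  fwrite_chr(dt, path)
}

#' Read acceleration samples from CSV
#'
#' Malformed rows, unparseable timestamps, duplicated or out-of-order
#' timestamps within a sow are rejected with the offending line number.
#'
#' @param path input file with header `sow_id,timestamp,x,y,z`.
#' @return named list of `accel_series`, one per sow.
#' @export
read_accel_csv <- function(path) {
  hdr <- names(fread(path, nrows = 0L))
  if (!identical(hdr, c("sow_id", "timestamp", "x", "y", "z")))
    stop(sprintf("%s: expected header sow_id,timestamp,x,y,z", path), call. = FALSE)
  dt <- fread(path, colClasses = list(character = c("sow_id", "timestamp"),
                                      numeric = c("x", "y", "z")))
  ts <- suppressWarnings(as.POSIXct(dt$timestamp, tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%OS"))
  bad <- which(is.na(ts) | is.na(dt$x) | is.na(dt$y) | is.na(dt$z))
  if (length(bad)) stop_row(path, bad[1L], "malformed row")
  dt[, timestamp := ts]
  out <- list()
  for (id in unique(dt$sow_id)) {
    sub <- dt[sow_id == id]
    tnum <- as.numeric(sub$timestamp)
    if (anyDuplicated(tnum)) {
      row <- which(dt$sow_id == id)[which(duplicated(tnum))[1L]]
      stop_row(path, row, sprintf("duplicated timestamp for sow %s", id))
    }
    if (is.unsorted(tnum, strictly = TRUE)) {
      row <- which(dt$sow_id == id)[which(diff(tnum) <= 0)[1L] + 1L]
      stop_row(path, row, sprintf("out-of-order timestamp for sow %s", id))
    }
    out[[id]] <- accel_series(id, sub[, list(timestamp, x, y, z)])
  }
  out
}

#' Write a cohort ground-truth manifest to CSV
#'
#' @param cohort a `sow_cohort`, list of scenarios, or a manifest data.table
#'   from [cohort_manifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(cohort, path) {
  mf <- if (is.data.frame(cohort)) as.data.table(cohort) else cohort_manifest(cohort)
  out <- copy(mf)
  for (col in c("housed_at", "calculated_farrowing", "true_onset", "surge_start"))
    out[, (col) := format_utc(get(col))]
  for (col in c("baseline_activity", "circadian_amplitude", "surge_multiplier",
                "dropout_rate", "day_effect_sd", "bout_sd", "bout_tau_minutes"))
    out[, (col) := num17(get(col))]
  fwrite_chr(out, path)
}

#' Read a cohort manifest from CSV
#'
#' @param path input file.
#' @return data.table with POSIXct time columns.
#' @export
read_manifest_csv <- function(path) {
  dt <- fread(path)
  for (col in c("housed_at", "calculated_farrowing", "true_onset", "surge_start"))
    dt[, (col) := as_utc(get(col), col)]
  dt
}

feature_long <- function(f) {
  data.table(sow_id = f$sow_id,
             interval_start = format_utc(interval_start(f$grid, seq_along(f$values) - 1L)),
             period_minutes = f$grid$period_minutes,
             characteristic = f$characteristic,
             value = num17(f$values),
             n_obs = f$n_obs)
}

#' Write feature series to long-format CSV
#'
#' All intervals from the grid origin are written, including missing ones, so
#' the grid is fully recoverable.
#'
#' @param features a `feature_series` or a (possibly nested) list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  if (inherits(features, "feature_series")) features <- list(features)
  flat <- list()
  collect <- function(x) for (e in x) {
    if (inherits(e, "feature_series")) flat[[length(flat) + 1L]] <<- e else collect(e)
  }
  collect(features)
  fwrite_chr(rbindlist(lapply(flat, feature_long)), path)
}

#' Read feature series from long-format CSV
#'
#' @param path input file.
#' @return nested list: `out[[sow_id]][[characteristic]]` per period present
#'   in the file; flattened names `sow.characteristic.period`.
#' @export
read_feature_csv <- function(path) {
  dt <- fread(path, colClasses = list(character = c("sow_id", "interval_start",
                                                    "characteristic")))
  req <- c("sow_id", "interval_start", "period_minutes", "characteristic",
           "value", "n_obs")
  if (!all(req %in% names(dt)))
    stop(sprintf("%s: expected feature columns %s", path,
                 paste(req, collapse = ",")), call. = FALSE)
  dt[, interval_start := as_utc(interval_start, "interval_start")]
  out <- list()
  splits <- split(dt, by = c("sow_id", "characteristic", "period_minutes"))
  for (sub in splits) {
    sub <- sub[order(interval_start)]
    period <- sub$period_minutes[1L]
    origin <- sub$interval_start[1L]
    grid <- interval_grid(period, origin)
    idx <- interval_index(grid, sub$interval_start)
    n <- max(idx) + 1L
    vals <- rep(NA_real_, n); nob <- rep(NA_integer_, n)
    vals[idx + 1L] <- suppressWarnings(as.numeric(sub$value))
    nob[idx + 1L] <- sub$n_obs
    key <- paste(sub$sow_id[1L], sub$characteristic[1L], period, sep = ".")
    out[[key]] <- feature_series(sub$sow_id[1L], sub$characteristic[1L],
                                 grid, vals, nob)
  }
  out
}

index_long <- function(x) {
  data.table(sow_id = x$sow_id,
             interval_start = format_utc(interval_start(x$grid, seq_along(x$values) - 1L)),
             period_minutes = x$grid$period_minutes,
             characteristic = x$characteristic,
             index_type = x$index_type,
             ma_range = x$ma_range,
             value = num17(x$values))
}

#' Write index series to long-format CSV
#'
#' @param indices an `index_series` or a (possibly nested) list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_index_csv <- function(indices, path) {
  if (inherits(indices, "index_series")) indices <- list(indices)
  flat <- list()
  collect <- function(x) for (e in x) {
    if (inherits(e, "index_series")) flat[[length(flat) + 1L]] <<- e else collect(e)
  }
  collect(indices)
  fwrite_chr(rbindlist(lapply(flat, index_long)), path)
}

#' Read index series from long-format CSV
#'
#' @param path input file.
#' @return named list of `index_series`
#'   (`sow.characteristic.index.r.period`).
#' @export
read_index_csv <- function(path) {
  dt <- fread(path, colClasses = list(character = c("sow_id", "interval_start",
                                                    "characteristic", "index_type")))
  dt[, interval_start := as_utc(interval_start, "interval_start")]
  out <- list()
  splits <- split(dt, by = c("sow_id", "characteristic", "index_type",
                             "ma_range", "period_minutes"))
  for (sub in splits) {
    sub <- sub[order(interval_start)]
    period <- sub$period_minutes[1L]
    grid <- interval_grid(period, sub$interval_start[1L])
    idx <- interval_index(grid, sub$interval_start)
    n <- max(idx) + 1L
    vals <- rep(NA_real_, n)
    vals[idx + 1L] <- suppressWarnings(as.numeric(sub$value))
    f <- feature_series(sub$sow_id[1L], sub$characteristic[1L], grid,
                        rep(NA_real_, n))
    ix <- index_series(f, sub$index_type[1L],
                       suppressWarnings(as.integer(sub$ma_range[1L])), vals)
    key <- paste(sub$sow_id[1L], sub$characteristic[1L], sub$index_type[1L],
                 ifelse(is.na(ix$ma_range), "r0", paste0("r", ix$ma_range)),
                 period, sep = ".")
    out[[key]] <- ix
  }
  out
}

#' Write a CUSUM chart trajectory to CSV
#'
#' @param result a `cusum_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cusum_csv <- function(result, path) {
  tab <- result$trajectory
  dt <- data.table(sow_id = result$sow_id,
                   interval_start = format_utc(tab$time),
                   x = num17(tab$x), cusum = num17(tab$cusum),
                   control_limit = num17(tab$control_limit),
                   alarm = as.integer(tab$alarm))
  fwrite_chr(dt, path)
}
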