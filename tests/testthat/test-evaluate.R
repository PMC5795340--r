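test_that("detection rates count first alarms inside the closed window", {
  expect_equal(detection_rate(rep(-6, 10), 12), 100)
  expect_equal(detection_rate(rep(NA_real_, 5), 48), 0)
  offs <- c(-3, -20, -50, NA)
  expect_equal(detection_rate(offs, 12), 25)
  expect_equal(detection_rate(offs, 48), 50)
  expect_equal(detection_rate(c(-12, -12.0001), 12), 50)  # closed boundary
  expect_error(detection_rate(numeric(0), 12), "empty cohort")
  expect_error(detection_rate(c(-1), 0), "positive")
})

test_that("cumulative detection curves are non-decreasing step functions", {
  one <- data.frame(k = 1, offset_hours = -10)
  cur <- cumulative_detection_curve(one, hours = seq(-12, 0, by = 1))
  expect_equal(cur[hours_before_onset == -11]$cum_pct, 0)
  expect_equal(cur[hours_before_onset == -10]$cum_pct, 100)
  expect_equal(cur[hours_before_onset == 0]$cum_pct, 100)

  set.seed(4)
  offs <- data.frame(k = rep(c(1, 5), each = 20),
                     offset_hours = replace(runif(40, -60, 0),
                                            sample(40, 8), NA))
  cur2 <- cumulative_detection_curve(offs)
  for (kk in c(1, 5))
    expect_true(all(diff(cur2[k == kk]$cum_pct) >= 0))
  # brute-force tabulation oracle at a few points
  for (t in c(-48, -20, -5)) {
    o <- offs$offset_hours[offs$k == 1]
    expect_equal(cur2[k == 1 & hours_before_onset == t]$cum_pct,
                 100 * mean(!is.na(o) & o <= t))
  }
})

test_that("evaluation config validates its grid", {
  expect_error(evaluation_config(windows_hours = c(-1, 12)), "positive")
  expect_error(evaluation_config(index_types = "Nope"), "arg")
  expect_error(evaluation_config(periods = 60, ma_ranges = list(`60` = 2L)),
               "inadmissible")
  ec <- evaluation_config(periods = 10L)
  expect_identical(ec$ma_ranges[["10"]], c(1L, 5L, 9L, 13L, 19L, 25L))
})

# a small shared cohort for the grid tests
small_cohort <- local({
  cfg <- cohort_config(2, seed = 33, onset_offset_days = c(-0.6, -0.1),
                       surge_lead_hours = c(14, 20))
  simulate_cohort(cfg)
})

test_that("a single-cell grid equals calling the detector directly", {
  ec <- evaluation_config(characteristics = "variation1",
                          index_types = "CumDi", periods = 60L,
                          ma_ranges = list(`60` = 1L), k_values = 5,
                          h_values = 4, scenarios = "m4")
  ev <- grid_search(small_cohort, ec)
  expect_identical(nrow(ev$cells), 2L)        # one cell x two windows
  for (entry in small_cohort) {
    sc <- entry$scenario
    f <- compute_features(entry$series, interval_grid(60, sc$housed_at),
                          "variation1")$variation1
    idx <- cumdi_index(f, 1)
    p <- fit_cusum_params(idx, sc$calculated_farrowing, "m4", k = 5, h = 4)
    res <- run_cusum(idx, p, end = sc$true_onset)
    want <- first_alarm_offset(res, sc$true_onset)
    got <- ev$offsets[sow_id == sc$sow_id]$offset_hours
    expect_identical(unique(got), want)
  }
  direct <- vapply(small_cohort, function(entry) {
    sc <- entry$scenario
    f <- compute_features(entry$series, interval_grid(60, sc$housed_at),
                          "variation1")$variation1
    idx <- cumdi_index(f, 1)
    p <- fit_cusum_params(idx, sc$calculated_farrowing, "m4", k = 5, h = 4)
    first_alarm_offset(run_cusum(idx, p, end = sc$true_onset), sc$true_onset)
  }, numeric(1))
  expect_equal(ev$cells[window_hours == 48]$detection_rate,
               detection_rate(direct, 48))
})

test_that("12 h rates never exceed 48 h rates and maxima dominate cells", {
  ec <- evaluation_config(characteristics = "variation1",
                          index_types = c("Orig", "Diff", "CumDi"),
                          periods = 60L, ma_ranges = list(`60` = c(1L, 3L)),
                          k_values = c(1, 5, 15), h_values = c(4, 8),
                          scenarios = "m4")
  ev <- grid_search(small_cohort, ec)
  wide <- dcast(ev$cells, characteristic + index_type + period + ma_range +
                  scenario + k + h ~ window_hours, value.var = "detection_rate")
  expect_true(all(wide$`12` <= wide$`48`))
  for (i in seq_len(nrow(ev$best))) {
    b <- ev$best[i]
    sub <- ev$cells[characteristic == b$characteristic &
                      index_type == b$index_type & period == b$period &
                      scenario == b$scenario & window_hours == b$window_hours]
    expect_true(all(sub$detection_rate <= b$detection_rate))
  }
  expect_true(all(ev$cells$n_detected <= ev$cells$n_evaluable))
})

test_that("grid search results are reproducible", {
  ec <- evaluation_config(characteristics = "variance", index_types = "Diff",
                          periods = 60L, ma_ranges = list(`60` = 1L),
                          k_values = c(1, 5), h_values = 4, scenarios = "m4")
  e1 <- grid_search(small_cohort, ec)
  e2 <- grid_search(small_cohort, ec)
  expect_identical(e1$cells, e2$cells)
  expect_identical(e1$offsets, e2$offsets)
})

test_that("unparameterizable sows are excluded from the denominator", {
  # second sow housed only on Day -4: its index has no Day -5 values and, for
  # baseline indices, none on Day -4 either (no prior day) -> excluded
  sc_ok <- quick_scenario(seed = 51, housed_days = 7)
  late <- sow_scenario("late", CF, CF - 8 * 3600, CF - 20 * 3600,
                       housed_at = CF - 4 * 86400 + 3600, seed = 52)
  cohort <- structure(list(
    list(scenario = sc_ok, series = simulate_sow(sc_ok)),
    list(scenario = late, series = simulate_sow(late))), class = "sow_cohort")
  ec <- evaluation_config(characteristics = "variation1",
                          index_types = c("Orig", "CumDi"), periods = 60L,
                          ma_ranges = list(`60` = 1L), k_values = 5,
                          h_values = 4, scenarios = c("m4", "m5"))
  ev <- grid_search(cohort, ec)
  counts <- unique(ev$cells[, list(index_type, scenario, n_evaluable, n_excluded)])
  # Orig m4 works for both sows; Orig m5 and all CumDi cells exclude the late sow
  expect_identical(counts[index_type == "Orig" & scenario == "m4"]$n_evaluable, 2L)
  expect_identical(counts[index_type == "Orig" & scenario == "m5"]$n_excluded, 1L)
  expect_identical(counts[index_type == "CumDi" & scenario == "m4"]$n_excluded, 1L)
})
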