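test_that("magnitude is the Euclidean norm and rejects non-finite input", {
  expect_equal(magnitude(3, 4, 0), 5)
  expect_equal(magnitude(0, 0, 0), 0)
  expect_equal(magnitude(1, 2, 2), 3)
  expect_equal(magnitude(c(3, 1), c(4, 2), c(0, 2)), c(5, 3))
  expect_error(magnitude(NaN, 0, 0), "finite")
  expect_error(magnitude(1, Inf, 0), "finite")
})

test_that("p-variation closed forms hold", {
  expect_equal(p_variation(rep(2.5, 4), 1), 0)
  expect_equal(p_variation(rep(2.5, 4), 3), 0)
  expect_equal(p_variation(c(0, 1, 0, 1), 1), 3)
  expect_equal(p_variation(c(0, 2, 0), 2), 8)
  expect_equal(p_variation(c(0, 2, 0), 3), 16)
  expect_identical(p_variation(5, 1), NA_real_)     # < 2 samples: missing
  expect_identical(p_variation(numeric(0), 2), NA_real_)
  expect_error(p_variation(c(0, 1), 4), "p must be")
})

test_that("single-interval characteristics match hand values", {
  # one 60-min interval holding magnitudes [1, 1, 1]
  s <- mags_series(c(1, 1, 1))
  f <- compute_features(s, interval_grid(60, T0),
                        c("mean", "variance", "variation1"))
  expect_equal(f$mean$values[1], 1)
  expect_equal(f$variance$values[1], 0)
  expect_equal(f$variation1$values[1], 0)

  # magnitudes [0, 2]: mean 1, sample variance 2 (n - 1 denominator), std √2
  s2 <- mags_series(c(0, 2))
  f2 <- compute_features(s2, interval_grid(60, T0),
                         c("mean", "variance", "std"))
  expect_equal(f2$mean$values[1], 1)
  expect_equal(f2$variance$values[1], 2)
  expect_equal(f2$std$values[1], sqrt(2))
})

test_that("empty series yields all-missing features", {
  s <- accel_series("e", data.frame(timestamp = as.POSIXct(character(), tz = UTC),
                                    x = numeric(), y = numeric(), z = numeric()))
  f <- compute_features(s, interval_grid(60, T0), "variance")
  expect_length(f$variance$values, 0)
})

test_that("every characteristic equals an independent recomputation", {
  s <- random_series(seed = 41, hours = 5, dropout = 0.2)
  for (period in c(10L, 60L)) {
    f <- compute_features(s, interval_grid(period, T0), all_characteristics(),
                          min_obs = 2L)
    parts <- oracle_partition(s, period)
    for (ch in all_characteristics()) {
      got <- f[[ch]]$values
      for (b in names(parts)) {
        x <- parts[[b]]
        want <- if (length(x) < 2) NA_real_ else oracle_stat(x, ch)
        pos <- as.integer(b) + 1L
        if (ch %in% c("mean", "variance", "std", "max", "median", "p25", "p75",
                      "variation1", "variation2", "variation3")) {
          expect_identical(got[pos], want)
        } else {
          expect_equal(got[pos], want, tolerance = 1e-12)
        }
      }
      expect_identical(f[[ch]]$n_obs,
                       unname(lengths(parts)[as.character(0:(length(got) - 1))]))
    }
  }
})

test_that("window statistics are consistent between grid and free windows", {
  s <- random_series(seed = 13, hours = 4)
  grid <- interval_grid(30, T0)
  f <- compute_features(s, grid, "variation2")
  for (i in c(0L, 3L, 7L)) {
    expect_identical(
      compute_feature_on_window(s, interval_start(grid, i),
                                interval_start(grid, i + 1L), "variation2"),
      f$variation2$values[i + 1L])
  }
  expect_identical(compute_feature_on_window(s, T0 + 40 * 3600, T0 + 41 * 3600,
                                             "mean"), NA_real_)
  expect_error(compute_feature_on_window(s, T0 + 10, T0 + 10, "mean"),
               "start must precede end")
})

test_that("extended windows match a brute-force oracle", {
  s <- random_series(seed = 77, hours = 6, dropout = 0.3)
  grid <- interval_grid(60, T0)
  ext <- farrowcast:::extended_feature_values(s, "variation1", grid, 10)
  for (i in seq_along(ext$values)) {
    lo <- interval_start(grid, i - 1L) - 600
    hi <- interval_start(grid, i) + 600
    sel <- s$data$timestamp >= lo & s$data$timestamp < hi
    m <- with(s$data[sel], sqrt(x^2 + y^2 + z^2))
    want <- if (length(m) < 2) NA_real_ else oracle_stat(m, "variation1")
    expect_identical(ext$values[i], want)
  }
})

test_that("statistics obey the scale laws", {
  s <- random_series(seed = 5, hours = 2, dropout = 0)
  a <- 3.7
  s2 <- accel_series("s1", within(as.data.frame(s$data), {
    x <- x * a; y <- y * a; z <- z * a
  }))
  g <- interval_grid(10, T0)
  f1 <- compute_features(s, g, all_characteristics())
  f2 <- compute_features(s2, g, all_characteristics())
  expect_equal(f2$std$values, a * f1$std$values, tolerance = 1e-12)
  expect_equal(f2$variance$values, a^2 * f1$variance$values, tolerance = 1e-12)
  expect_equal(f2$variation1$values, a * f1$variation1$values, tolerance = 1e-12)
  expect_equal(f2$variation2$values, a^2 * f1$variation2$values, tolerance = 1e-12)
  expect_equal(f2$variation3$values, a^3 * f1$variation3$values, tolerance = 1e-12)
  expect_equal(f2$skewness$values, f1$skewness$values, tolerance = 1e-9)
  expect_equal(f2$kurtosis$values, f1$kurtosis$values, tolerance = 1e-9)
})

test_that("variation1 is zero iff all window samples are equal", {
  expect_identical(p_variation(rep(0.123, 50), 1), 0)
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(20)
    expect_gt(p_variation(x, 1), 0)
  }
})

test_that("intervals below min_obs stay missing when samples are removed", {
  s <- mags_series(c(1, 2, 3))
  g <- interval_grid(60, T0)
  f3 <- compute_features(s, g, "variance", min_obs = 3L)
  expect_false(is.na(f3$variance$values[1]))
  s2 <- mags_series(c(1, 2))          # one sample removed
  f2 <- compute_features(s2, g, "variance", min_obs = 3L)
  expect_true(is.na(f2$variance$values[1]))
  s1 <- mags_series(1)
  f1 <- compute_features(s1, g, "variance", min_obs = 2L)
  expect_true(is.na(f1$variance$values[1]))
})
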