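test_that("admissible moving-average ranges and overlaps are enforced", {
  expect_identical(ma_ranges_for(60), c(1L, 3L, 5L))
  expect_identical(ma_ranges_for(30), c(1L, 3L, 5L, 9L))
  expect_identical(ma_ranges_for(10), c(1L, 5L, 9L, 13L, 19L, 25L))
  expect_identical(overlap_for(60), 10L)
  expect_identical(overlap_for(30), 5L)
  expect_identical(overlap_for(10), 2L)
  f <- make_feature(rep(1, 100))
  expect_error(diff_index(f, 2), "r admissible")
  expect_error(baseline_ma(f, 30L, 9), "r admissible")
})

test_that("baseline is the previous-day centred moving average", {
  f <- make_feature(rep(5, 80))
  expect_equal(baseline_ma(f, 40L, 1), 5)
  expect_equal(baseline_ma(f, 40L, 5), 5)
  expect_true(is.na(baseline_ma(f, 24L, 1)))   # i < T + r: no previous day
  expect_false(is.na(baseline_ma(f, 25L, 1)))

  set.seed(31)
  v <- rnorm(200)
  v[sample(200, 40)] <- NA
  fr <- make_feature(v)
  for (r in c(1L, 3L, 5L)) {
    i <- 0:199
    expect_identical(baseline_ma(fr, i, r), oracle_baseline(v, 24L, r, i))
  }
})

test_that("baseline goes missing when under half its window is defined", {
  v <- rep(2, 60)
  v[26:28] <- NA          # intervals 25..27 of day 1
  f <- make_feature(v)
  # r = 1: window around slot 26 of day 1 = intervals 25..27, 1 of 3 defined
  expect_true(is.na(baseline_ma(f, 26L + 24L, 1L)))
  # r = 3: window 23..29 has 4 of 7 defined >= ceil(7/2) -> defined
  expect_false(is.na(baseline_ma(f, 26L + 24L, 3L)))
})

test_that("Diff and Quot reproduce day-over-day contrasts", {
  # previous day constant 5, current day constant 7
  f <- make_feature(c(rep(5, 24), rep(7, 24)))
  for (r in c(1L, 3L, 5L)) {
    d <- diff_index(f, r)
    q <- quot_index(f, r)
    mid <- 36L + 1L   # mid-day slot: baseline window stays inside day 0
    expect_equal(d$values[mid], 2)
    expect_equal(q$values[mid], 7 / 5)
    expect_true(all(is.na(d$values[seq_len(24 + r)])))
  }
})

test_that("a zero baseline yields missing, never infinity", {
  f <- make_feature(c(rep(0, 24), rep(3, 24)))
  q <- quot_index(f, 1)
  # mid-day slots have an all-zero baseline window -> guarded to missing
  expect_true(all(is.na(q$values[30:44])))
  expect_false(any(is.infinite(q$values), na.rm = TRUE))
})

test_that("day-flat periodic series cancel exactly for every admissible r", {
  for (period in c(10L, 30L, 60L)) {
    T_day <- 1440L / period
    f <- periodic_feature(rep(4.2, T_day), days = 4, period = period)
    for (r in ma_ranges_for(period)) {
      d <- diff_index(f, r)$values
      q <- quot_index(f, r)$values
      cd <- cumdi_index(f, r)$values
      cq <- cumq_index(f, r)$values
      expect_identical(unique(d[!is.na(d)]), 0)
      expect_identical(unique(cd[!is.na(cd)]), 0)
      expect_equal(unique(q[!is.na(q)]), 1)
      # CumQ counts the defined intervals: slope exactly 1
      expect_equal(diff(cq[!is.na(cq)]), rep(1, sum(!is.na(cq)) - 1L))
    }
  }
})

test_that("nonconstant periodic series match the centred-MA residual oracle", {
  # with a day-offset MA baseline, a 24 h-periodic series cancels up to the
  # moving-average smoothing residual F(i) - centred MA of F at i; the index
  # must equal that residual exactly
  for (period in c(30L, 60L)) {
    T_day <- 1440L / period
    prof <- 5 + sin(2 * pi * seq_len(T_day) / T_day)
    f <- periodic_feature(prof, days = 3, period = period)
    for (r in ma_ranges_for(period)) {
      d <- diff_index(f, r)$values
      want <- f$values - oracle_baseline(f$values, T_day, r, seq_along(f$values) - 1L)
      expect_identical(d, want)
    }
  }
})

test_that("Over with zero overlap equals Quot computed from features", {
  s <- random_series(seed = 3, hours = 30, dropout = 0.1)
  grid <- interval_grid(60, T0)
  f <- compute_features(s, grid, "variation1")$variation1
  ov <- over_index(s, "variation1", grid, 1, overlap_minutes = 0)
  q <- quot_index(f, 1)
  expect_identical(ov$values, q$values)
  expect_identical(ov$index_type, "Over")
})

test_that("Over matches a brute-force extended-window oracle", {
  s <- random_series(seed = 12, hours = 30, dropout = 0.2)
  grid <- interval_grid(60, T0)
  ov <- over_index(s, "variance", grid, 1)
  n <- length(ov$values)
  g_or <- vapply(seq_len(n) - 1L, function(i)
    compute_feature_on_window(s, interval_start(grid, i) - 600,
                              interval_start(grid, i + 1L) + 600, "variance"),
    numeric(1))
  want <- g_or / oracle_baseline(g_or, 24L, 1L, seq_len(n) - 1L)
  expect_equal(ov$values, want, tolerance = 1e-14)
})

test_that("cumulative indices accumulate as specified", {
  # Diff constant c from the first defined interval: CumDi grows linearly
  f <- make_feature(c(rep(2, 24), rep(5, 48)))
  cd <- cumdi_index(f, 1)
  def <- which(!is.na(cd$values))
  mid <- def[def >= 36 & def <= 44]          # slots with all-2 baselines
  expect_equal(diff(cd$values[mid]), rep(3, length(mid) - 1L))

  # CumQ slope doubles when Quot doubles
  fq <- make_feature(c(rep(2, 24), rep(2, 12), rep(4, 12), rep(4, 24)))
  cq <- cumq_index(fq, 1)
  expect_equal(cq$values[32] - cq$values[31], 1)   # Quot = 1 region
  expect_equal(cq$values[44] - cq$values[43], 2)   # Quot = 2 region

  # CumAv: flat series stays 0, a step up makes it grow
  fa <- make_feature(rep(3, 72))
  ca <- cumav_index(fa)
  expect_identical(unique(ca$values[!is.na(ca$values)]), 0)
  fs <- make_feature(c(rep(3, 48), rep(4, 24)))
  cs <- cumav_index(fs)
  expect_gt(cs$values[72], cs$values[49])
  expect_true(all(diff(cs$values[49:72]) > 0))
})

test_that("missing terms contribute zero to cumulative sums", {
  v <- c(rep(2, 24), rep(2, 6), NA, NA, rep(2, 16))
  f <- make_feature(v)
  cd <- cumdi_index(f, 1)
  def <- !is.na(cd$values)
  expect_identical(unique(cd$values[def]), 0)
  # the NA intervals still carry the running value forward
  expect_identical(cd$values[31], cd$values[30])
})

test_that("indices agree with brute-force oracles on random series", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 120L
    v <- exp(rnorm(n))                      # positive, index-friendly
    v[sample(n, 15)] <- NA
    f <- make_feature(v)
    for (r in c(1L, 3L)) {
      b <- oracle_baseline(v, 24L, r, seq_len(n) - 1L)
      d_want <- v - b
      q_want <- v / ifelse(abs(b) < 1e-12, NA, b)
      expect_identical(diff_index(f, r)$values, d_want)
      expect_equal(quot_index(f, r)$values, q_want, tolerance = 1e-15)
      # cumulative oracles
      cum_or <- function(x) {
        def <- which(!is.na(x))
        if (!length(def)) return(rep(NA_real_, length(x)))
        out <- rep(NA_real_, length(x))
        acc <- 0
        for (i in def[1]:length(x)) {
          if (!is.na(x[i])) acc <- acc + x[i]
          out[i] <- acc
        }
        out
      }
      expect_identical(cumdi_index(f, r)$values, cum_or(d_want))
      expect_equal(cumq_index(f, r)$values, cum_or(q_want), tolerance = 1e-15)
    }
    # CumAv oracle
    ca_want <- local({
      term <- rep(NA_real_, n)
      for (p in seq_len(n)) {
        if (p <= 24L || is.na(v[p])) next
        w <- v[(p - 24L):(p - 1L)]
        if (sum(!is.na(w)) < 12L) next
        term[p] <- v[p] - mean(w, na.rm = TRUE)
      }
      def <- which(!is.na(term))
      out <- rep(NA_real_, n)
      if (length(def)) {
        acc <- 0
        for (i in def[1]:n) {
          if (!is.na(term[i])) acc <- acc + term[i]
          out[i] <- acc
        }
      }
      out
    })
    expect_identical(cumav_index(f)$values, ca_want)
  }
})

test_that("Diff is invariant to additive shifts and equivariant to scale", {
  set.seed(17)
  v <- rnorm(150)
  f <- make_feature(v)
  fc <- make_feature(v + 11.5)
  expect_equal(diff_index(fc, 3)$values, diff_index(f, 3)$values,
               tolerance = 1e-12)
  fa <- make_feature(2.5 * v)
  expect_equal(diff_index(fa, 3)$values, 2.5 * diff_index(f, 3)$values,
               tolerance = 1e-12)
  vpos <- exp(v)
  expect_equal(quot_index(make_feature(3 * vpos), 3)$values,
               quot_index(make_feature(vpos), 3)$values, tolerance = 1e-12)
})

test_that("Quot is smoother than Diff on a pre-surge synthetic day", {
  sc <- quick_scenario(seed = 21, lead_h = 14)
  s <- simulate_sow(sc)
  f <- compute_features(s, interval_grid(60, sc$housed_at), "variation1")$variation1
  d <- diff_index(f, 1)$values
  q <- quot_index(f, 1)$values
  pre <- 25:48        # day after the baseline day, before any surge
  expect_lt(var(q[pre], na.rm = TRUE), var(d[pre], na.rm = TRUE))
  cq <- cumq_index(f, 1)$values
  qv <- q; qv[is.na(qv)] <- 0
  if (all(qv >= 0)) expect_true(all(diff(cq[!is.na(cq)]) >= 0))
})

test_that("compute_index dispatches and validates", {
  f <- make_feature(rep(1, 60))
  expect_error(compute_index(f, "Diff"), "requires ma_range")
  expect_error(compute_index(f, "Over", 1), "raw")
  expect_identical(compute_index(f, "Orig")$values, f$values)
  expect_error(compute_index(f, "Nope"), "arg")
})
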