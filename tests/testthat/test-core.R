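test_that("relative length matches direct evaluation of the hypotenuse", {
  ts <- mafdm_ts(c(0, 1, 0, 1, 0), f0 = 1)
  expect_equal(relative_length_at_level(ts, 1, 1, 1), sqrt(2))
  # zero amplitude differential: exactly the time base, R = 1
  ts2 <- mafdm_ts(c(0, 1, 0), f0 = 1)
  expect_identical(relative_length_at_level(ts2, 1, 2, 1),
                   (1 / 2) * sqrt(0 + 4))
  # n = 2 diagonal over a rise of 1
  ts3 <- mafdm_ts(c(0, 0.3, 1), f0 = 1)
  expect_equal(relative_length_at_level(ts3, 1, 2, 1),
               (1 / 2) * sqrt(1 + 4))
  expect_error(relative_length_at_level(ts2, 2, 2, 1), "out of range")
  expect_error(relative_length_at_level(ts2, 1, 1, -1), "positive")
})

test_that("relative length is never below 1", {
  set.seed(21)
  for (rep in 1:20) {
    ts <- mafdm_ts(stats::rnorm(30), f0 = stats::runif(1, 0.1, 100))
    n <- sample(c(1L, 2L, 4L), 1)
    m <- 10^stats::runif(1, -6, 6)
    i <- sample(30L - n, 1)
    expect_gte(relative_length_at_level(ts, i, n, m), 1)
  }
})

test_that("windowed relative length reproduces the boundary algebra", {
  # constant window: interior sum w-n+1, boundary weights n-1, total w/n
  flat <- mafdm_ts(rep(2.5, 40), f0 = 3)
  for (n in c(1L, 2L, 4L)) {
    expect_equal(windowed_relative_length(flat, 9, 16, n, m = 7), 16 / n,
                 tolerance = 1e-14)
  }
  # alternating wave at n = 1: four identical sqrt(2) segments
  alt <- mafdm_ts(rep_len(c(0, 1), 20), f0 = 1)
  expect_equal(windowed_relative_length(alt, 5, 4, 1, 1), 4 * sqrt(2))
  # n = 2 decimation flattens the alternation: every R_i = 1, total w/n
  expect_equal(windowed_relative_length(alt, 5, 4, 2, 1), 2.0)
})

test_that("full_context errors name the missing samples", {
  ts <- mafdm_ts(rep(0, 20), f0 = 1)
  err <- tryCatch(windowed_relative_length(ts, 1, 10, 4, 1),
                  error = conditionMessage)
  expect_match(err, "missing 3 sample\\(s\\) on the left")
  err <- tryCatch(windowed_relative_length(ts, 10, 10, 4, 1),
                  error = conditionMessage)
  expect_match(err, "3 on the right")
  # truncate needs no context and stays exact on constants
  expect_equal(windowed_relative_length(ts, 1, 10, 4, 1,
                                        edge_policy = "truncate"), 10 / 4)
})

test_that("fit_dimension recovers gradient, intercept and correlation", {
  # flat-signal points are collinear with slope 1 by construction
  est <- fit_dimension(list(n = c(1, 2, 4), R = c(100, 50, 25)), f0 = 1)
  expect_equal(est$D_Hm, 1, tolerance = 1e-12)
  expect_equal(abs(est$r), 1, tolerance = 1e-12)
  # two-level triangular points equal the closed-form gradient
  est2 <- fit_dimension(list(n = c(1, 3),
                             R = c(3 * sqrt(2), sqrt(10) / 3)), f0 = 1)
  expect_equal(est2$D_Hm, triangular_gradient_direct(1, 1, 1, 3),
               tolerance = 1e-14)
  # equal lengths at all scales: a horizontal log-log line, D = 0
  est3 <- fit_dimension(list(n = c(1, 2, 4), R = c(7, 7, 7)), f0 = 1)
  expect_equal(est3$D_Hm, 0)
  expect_true(is.na(est3$r))
  # non-positive windowed length: degenerate NaN, not an error
  est4 <- fit_dimension(list(n = c(1, 2), R = c(3, 0)), f0 = 1)
  expect_true(is.nan(est4$D_Hm))
  expect_identical(est4$flag, "degenerate")
  expect_error(fit_dimension(list(n = 1, R = 3), 1), "two distinct")
})

test_that("window_dimension equals the triangular closed form", {
  alt <- mafdm_ts(rep_len(c(0, 1), 40), f0 = 1)
  cfg <- estimator_config(m = 1, levels = c(1, 3), w = 12)
  expect_equal(window_dimension(alt, 4, cfg)$D_Hm,
               triangular_gradient_direct(1, 1, 1, 3),
               tolerance = 1e-12)
  # huge multiplier drives the estimate to the filled-area asymptote
  cfg2 <- estimator_config(m = 1e9, levels = c(1, 3), w = 12)
  expect_equal(window_dimension(alt, 4, cfg2)$D_Hm, 2, tolerance = 1e-6)
})

test_that("constant windows give D_Hm = 1 exactly for any m and levels", {
  set.seed(5)
  for (rep in 1:25) {
    level0 <- stats::runif(1, -50, 50)
    f0 <- 10^stats::runif(1, -2, 3)
    m <- 10^stats::runif(1, -8, 8)
    levels <- sample(list(c(1L, 2L), c(1L, 2L, 4L), c(1L, 3L, 9L),
                          c(1L, 2L, 4L, 8L)), 1)[[1]]
    w <- 4L * max(levels) + sample(0:20, 1)
    n_samp <- w + 2L * max(levels) + 10L
    ts <- mafdm_ts(rep(level0, n_samp), f0 = f0)
    cfg <- estimator_config(m = m, levels = levels, w = w)
    est <- window_dimension(ts, max(levels) + 1L, cfg)
    expect_lt(abs(est$D_Hm - 1), 1e-9)
    expect_equal(abs(est$r), 1, tolerance = 1e-9)
  }
})

test_that("amplitude scale and multiplier enter only as their product", {
  ts <- random_walk_ts(150, f0 = 20, seed = 33)
  cfg <- function(m) estimator_config(m = m, levels = c(1, 2, 4), w = 40)
  for (c_scale in c(0.01, 9.81, 120)) {
    scaled <- mafdm_ts(c_scale * ts$values, f0 = ts$f0)
    d1 <- window_dimension(scaled, 10, cfg(0.7))$D_Hm
    d2 <- window_dimension(ts, 10, cfg(0.7 * c_scale))$D_Hm
    expect_lt(abs(d1 - d2), 1e-12)
  }
})

test_that("offset and time reversal leave the estimate unchanged", {
  ts <- random_walk_ts(150, f0 = 20, seed = 34)
  cfg <- estimator_config(m = 2, levels = c(1, 2, 4), w = 40)
  d0 <- window_dimension(ts, 20, cfg)$D_Hm
  shifted <- mafdm_ts(ts$values + 123.45, f0 = ts$f0)
  expect_lt(abs(window_dimension(shifted, 20, cfg)$D_Hm - d0), 1e-12)
  # mirror the whole series; the mirrored window covers the same samples
  rev_ts <- mafdm_ts(rev(ts$values), f0 = ts$f0)
  j_rev <- length(ts$values) - (20 + cfg$w) + 1L
  expect_lt(abs(window_dimension(rev_ts, j_rev, cfg)$D_Hm - d0), 1e-12)
})

test_that("small and large multipliers reach the analytic limits", {
  for (seed in 1:5) {
    ts <- random_walk_ts(160, f0 = 30, seed = seed)
    # |dy| * f0 stays well under 1e3 for a unit-step random walk at f0=30
    cfg_small <- estimator_config(m = 1e-9, levels = c(1, 2, 4), w = 48)
    expect_lt(window_dimension(ts, 8, cfg_small)$D_Hm - 1, 1e-4)
    s <- 1 / max(abs(diff(ts$values)))
    cfg_large <- estimator_config(m = 1e9 * s, levels = c(1, 2, 4), w = 48)
    mono <- mono_dimensional_dimension(ts, 8, 48, c(1, 2, 4))
    expect_lt(abs(window_dimension(ts, 8, cfg_large)$D_Hm - mono$D_Hm),
              1e-6)
  }
})

test_that("sliding series agrees with window-by-window evaluation", {
  ts <- random_walk_ts(120, f0 = 10, seed = 8)
  for (edge in c("full_context", "truncate")) {
    cfg <- estimator_config(m = 0.5, levels = c(1, 2, 4), w = 30,
                            edge_policy = edge)
    fd <- sliding_dimension(ts, cfg)
    starts <- attr(fd, "start_index")
    direct <- vapply(starts, function(j)
      window_dimension(ts, j, cfg)$D_Hm, numeric(1))
    expect_equal(fd$D_Hm, direct, tolerance = 1e-12)
    expect_equal(fd$center_index, starts + cfg$w %/% 2L)
    expect_true(all(diff(fd$center_index) == 1L))
  }
})

test_that("sliding series tracks a flat-to-alternating transition", {
  ts <- mafdm_ts(c(rep(0, 500), rep_len(c(0, 1), 500)), f0 = 1)
  cfg <- estimator_config(m = 1, levels = c(1, 3), w = 100)
  fd <- sliding_dimension(ts, cfg)
  d_alt <- triangular_gradient_direct(1, 1, 1, 3)
  flat_part <- fd$D_Hm[fd$center_index <= 400]
  alt_part <- fd$D_Hm[fd$center_index >= 600]
  expect_true(all(abs(flat_part - 1) < 1e-9))
  expect_true(all(abs(alt_part - d_alt) < 1e-9))
  # transition stays bracketed by the two plateaus (small boundary-term
  # wiggles of ~1e-4 aside); windows actually straddling the boundary
  # (centers within w/2 of sample 500) rise monotonically in trend
  trans <- fd$D_Hm[fd$center_index > 400 & fd$center_index < 600]
  expect_true(all(trans > 1 - 1e-3 & trans < d_alt + 1e-3))
  mix <- fd$D_Hm[fd$center_index > 450 & fd$center_index < 550]
  expect_gt(stats::cor(mix, seq_along(mix)), 0.99)
  expect_error(sliding_dimension(mafdm_ts(rep(0, 50), 1), cfg),
               "shorter than one window")
})

test_that("estimator_config rejects malformed level sets and windows", {
  expect_error(estimator_config(levels = c(1, 2, 3, 4), w = 100),
               "log-equidistant")
  expect_error(estimator_config(levels = c(2, 4), w = 100), "first level")
  expect_error(estimator_config(levels = c(1), w = 100), "at least 2")
  expect_error(estimator_config(levels = c(1, 2, 4), w = 10), ">= 4")
  expect_error(estimator_config(m = 0, w = 100), "positive")
  expect_silent(estimator_config(levels = c(1, 3, 9), w = 36))
})
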