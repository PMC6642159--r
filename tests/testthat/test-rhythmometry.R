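test_that("cosinor recovers noise-free rhythms in the basis exactly", {
  cases <- list(
    list(mesor = 10, amp = 6.2, acro = 10.5, period = 24),
    list(mesor = 3,  amp = 1.1, acro = 22.7, period = 24),
    list(mesor = 50, amp = 12,  acro = 5.0,  period = 12))
  for (cs in cases) {
    tr <- make_cosinor_tr(cs$mesor, cs$amp, cs$acro, cs$period)
    f <- fit_cosinor(tr)
    k <- match(cs$period, f$components$period)
    expect_equal(f$mesor, cs$mesor, tolerance = 1e-10)
    expect_equal(f$components$amplitude[k], cs$amp, tolerance = 1e-10)
    expect_lt(circular_distance(f$components$acrophase[k], cs$acro,
                                cs$period), 1e-8)
    expect_lt(f$residual_ss, 1e-16)
    # only the generating component explains variance
    expect_lt(f$components$p_value[k], 0.05)
  }
})

test_that("cosinor predictions evaluate mesor plus components", {
  f0 <- cosinor_truth(1)
  expect_equal(predict_cosinor(f0, 7), 1)
  f1 <- cosinor_truth(0, 24, 1, 0)
  expect_equal(predict_cosinor(f1, 0), 1)
  expect_equal(predict_cosinor(f1, 12), -1)
  tr <- make_cosinor_tr(10, 6.2, 10.5)
  f <- fit_cosinor(tr)
  expect_equal(predict_cosinor(f, 10.5), 16.2, tolerance = 1e-8)
})

test_that("adding a harmonic never increases the residual sum of squares", {
  set.seed(11)
  for (i in 1:20) {
    vals <- lapply(zt_grid, function(z) rnorm(5, 10, 2))
    tr <- timed_replicates(zt_grid, vals)
    rss <- vapply(list(24, c(24, 12), c(24, 12, 8)), function(per)
      fit_cosinor(tr, periods = per)$residual_ss, numeric(1))
    expect_true(all(diff(rss) <= 1e-10))
  }
})

test_that("under-determined designs and constant input are handled", {
  tr <- timed_replicates(c(0, 6, 12, 18), lapply(1:4, function(i) rep(1, 3)))
  expect_error(fit_cosinor(tr), "under-determined")
  flat <- timed_replicates(zt_grid, lapply(zt_grid, function(z) rep(5, 4)))
  f <- fit_cosinor(flat)
  expect_equal(unname(f$components$amplitude), rep(0, 3), tolerance = 1e-12)
  expect_equal(f$components$p_value, rep(1, 3))
})

test_that("zero-amplitude F-test holds its nominal size approximately", {
  # reduced null simulation; the full 1000-run check is in the acceptance
  # suite
  set.seed(21)
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    tr <- timed_replicates(zt_grid, lapply(zt_grid, function(z) rnorm(5)))
    hits <- hits + (fit_cosinor(tr)$components$p_value[1] < 0.05)
  }
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(hits / reps, ci[1] - 1e-9)
  expect_lt(hits / reps, ci[2] + 1e-9)
})

test_that("detrending removes lines and normalizes to mean 1", {
  t <- seq(0, 96, by = 0.5)
  expect_equal(detrend_normalize(t, 2 + 0.1 * t), rep(1, length(t)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # idempotence on a series with zero OLS slope and mean 1
  y_raw <- 1 + 0.2 * sin(2 * pi * t / 7.3)
  m <- mean(y_raw)
  y <- (stats::resid(lm(y_raw ~ t)) + m) / m
  expect_equal(detrend_normalize(t, y), y, tolerance = 1e-10,
               ignore_attr = TRUE)
  # relative amplitude preserved on a grid symmetric over whole periods
  t24 <- seq(0.125, 48 - 0.125, by = 0.25)
  y5 <- 5 * (1 + 0.5 * cos(2 * pi * t24 / 24))
  expect_equal(detrend_normalize(t24, y5), 1 + 0.5 * cos(2 * pi * t24 / 24),
               tolerance = 1e-10, ignore_attr = TRUE)
  # output mean is 1 to near machine precision for arbitrary input
  set.seed(3)
  yr <- exp(rnorm(200))
  expect_equal(mean(detrend_normalize(seq_along(yr), yr)), 1,
               tolerance = 1e-12)
  expect_error(detrend_normalize(t, -1 + 0 * t), "positive")
})

test_that("damped cosine fit is exact on noise-free model-form series", {
  for (truth in biolum_truth) {
    s <- make_damped_series(truth)
    f <- fit_damped_cosine(s$t, s$y, seed = 1)
    expect_equal(f$period, truth$period, tolerance = 1e-6)
    expect_equal(f$relative_amplitude, truth$rel_amplitude, tolerance = 1e-6)
    expect_equal(f$acrophase, truth$acrophase, tolerance = 1e-5)
    expect_equal(f$damping_rate, truth$damping_rate, tolerance = 1e-4)
    expect_false(f$degenerate)
  }
})

test_that("damped cosine optimum beats every multi-start initial point", {
  s <- make_damped_series(biolum_truth$male)
  set.seed(5)
  y <- s$y + rnorm(length(s$y), 0, 0.05)
  f <- fit_damped_cosine(s$t, y, seed = 2)
  expect_true(all(f$residual_ss <= f$start_objectives + 1e-9))
})

test_that("flat series is flagged degenerate", {
  t <- seq(0, 143.9, by = 1 / 6)
  f <- fit_damped_cosine(t, rep(1, length(t)), seed = 1)
  expect_true(f$degenerate)
  expect_lt(f$relative_amplitude, 1e-3)
  expect_true(is.na(f$acrophase))
})

test_that("phases are compared on the circle", {
  expect_equal(circular_distance(23.5, 0.5, 24), 1)
  expect_equal(circular_distance(1, 13, 24), 12)
  expect_equal(circular_distance(5, 5, 12), 0)
})
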