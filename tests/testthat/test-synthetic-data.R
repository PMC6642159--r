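test_that("expression generator is exact at zero noise and seeded", {
  des <- experiment_design()
  truth <- cosinor_truth(10, 24, 6.2, 15)
  tr0 <- gen_expression(des, truth, noise_model(expression_cv = 0), seed = 1)
  for (i in seq_along(tr0$zt_hours))
    expect_equal(tr0$values_per_zt[[i]],
                 rep(predict_cosinor(truth, tr0$zt_hours[i]), 5))
  t1 <- gen_expression(des, truth, seed = 42)
  t2 <- gen_expression(des, truth, seed = 42)
  expect_identical(t1, t2)
  expect_false(identical(t1, gen_expression(des, truth, seed = 43)))
})

test_that("expression round trip recovers the generating rhythm", {
  des <- experiment_design()
  truth <- cosinor_truth(10, 24, 6.2, 15)  # 62% relative amplitude
  tr <- gen_expression(des, truth, noise_model(expression_cv = 0.2),
                       seed = 7)
  f <- fit_cosinor(tr)
  expect_equal(f$components$amplitude[1] / f$mesor, 0.62, tolerance = 0.15)
  expect_lt(circular_distance(f$components$acrophase[1], 15, 24), 1.5)
  expect_lt(f$components$p_value[1], 0.05)
})

test_that("PK generator has destructive structure and respects the floor", {
  des <- experiment_design(n_mice_per_time = 4)
  truth <- reference_parameters()
  dat <- gen_pk_experiment(des, truth, noise_model(0, 0, 0), seed = 1)
  expect_length(dat, 2)
  expect_equal(vapply(dat, function(g) g$zt_dose, numeric(1)), c(3, 15))
  # zero noise: every mouse sits on the deterministic curve
  g <- dat[[1]]
  sim <- simulate_pbpk(truth, dose_event(zt_dose = 3),
                       times = c(0, g$times))
  for (j in seq_along(g$times))
    expect_equal(g$conc$plasma[[j]],
                 rep(sim$concentrations[j + 1, "plasma"], 4),
                 tolerance = 1e-8, ignore_attr = TRUE)
  # censoring: low-dose regime pushes late plasma below 0.05 ug/mL
  low <- truth; low$renal$mean_rate <- 20
  datc <- gen_pk_experiment(des, low, noise_model(0, 0.1, 0.05), seed = 2,
                            dose_mg_per_kg = 0.1)
  cens <- attr(datc[[1]], "censored")
  flagged <- unlist(cens$plasma)
  vals <- unlist(datc[[1]]$conc$plasma)
  expect_true(any(flagged))
  expect_true(all(vals[flagged] == 0.05))
  expect_true(all(vals >= 0.05 - 1e-12 | !flagged))
})

test_that("PK generator round-trips through calibration", {
  fx <- make_estimation_fixture(seed = 31, cv = 0, max_evals = 1200)
  fit <- fit_group(fx$data, fx$cfg, seed = 3,
                   theta0 = fx$true_theta * c(rep(2, 7), 1))
  rates <- setdiff(names(fx$true_theta), "renal_phase")
  expect_true(all(abs(fit$theta[rates] / fx$true_theta[rates] - 1) < 0.05))
})

test_that("bioluminescence generator matches its design and truth", {
  des <- experiment_design()  # 144 h at 10-min sampling
  df <- gen_bioluminescence(des, 24, 1.27, 19.22, 0.0054, seed = 1)
  expect_equal(nrow(df), 864)
  # zero trend/noise: normalization by the sample mean then damped-cosine
  # fit recovers the truth closely (linear detrending of a finite damped
  # record carries a small intrinsic bias)
  yn <- detrend_normalize(df$t_h, df$counts)
  f <- fit_damped_cosine(df$t_h, yn, seed = 1)
  expect_equal(f$period, 24, tolerance = 0.002)
  expect_equal(f$relative_amplitude, 1.27, tolerance = 0.02)
  expect_lt(circular_distance(f$acrophase, 19.22, f$period), 0.1)
  # with trend and noise the trend is removed before fitting
  nm <- noise_model(biolum_sd = 20, biolum_trend_slope = -2)
  dfn <- gen_bioluminescence(des, 24, 1.27, 19.22, 0.0054,
                             noise = nm, seed = 2)
  f2 <- fit_damped_cosine(dfn$t_h, detrend_normalize(dfn$t_h, dfn$counts),
                          seed = 1)
  expect_equal(f2$period, 24, tolerance = 0.02)
})

test_that("female and male study settings separate in period", {
  des <- experiment_design()
  nm <- noise_model(biolum_sd = 20, biolum_trend_slope = -1)
  fits <- lapply(biolum_truth, function(tt) {
    df <- gen_bioluminescence(des, tt$period, tt$rel_amplitude,
                              tt$acrophase, tt$damping_rate,
                              noise = nm, seed = 5)
    fit_damped_cosine(df$t_h, detrend_normalize(df$t_h, df$counts),
                      seed = 1)
  })
  expect_gt(fits$male$period - fits$female$period, 2)
})
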