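test_that("objective is zero at the truth for scatter-free data", {
  fx <- make_estimation_fixture(seed = 1, cv = 0)
  expect_lt(pk_objective(fx$true_theta, fx$data, fx$cfg), 1e-10)
})

test_that("objective matches a directly computed weighted sum of squares", {
  fx <- make_estimation_fixture(seed = 2, cv = 0.2)
  theta <- fx$true_theta * 1.3
  theta["renal_phase"] <- 14
  # independent recomputation: simulate, then accumulate the formula
  p <- apply_theta(fx$cfg, theta)
  allobs <- function(m) unlist(lapply(fx$data, function(g)
    unlist(g$conc[[m]])), use.names = FALSE)
  expected <- 0
  for (g in fx$data) {
    sim <- simulate_pbpk(p, dose_event(zt_dose = g$zt_dose),
                         times = c(0, g$times))
    for (m in c("plasma", "ileum", "liver")) {
      w <- 1 / mean(allobs(m))^2
      for (j in seq_along(g$times)) {
        pred <- sim$concentrations[j + 1, m]
        expected <- expected + w * sum((pred - g$conc[[m]][[j]])^2)
      }
    }
  }
  expect_equal(pk_objective(theta, fx$data, fx$cfg), expected,
               tolerance = 1e-10)
})

test_that("objective scales quadratically and ignores replicate order", {
  fx <- make_estimation_fixture(seed = 3, cv = 0)
  # perturb observations by +d and +2d around the exact model curve
  perturb <- function(dat, f) lapply(dat, function(g) {
    for (m in c("plasma", "ileum", "liver"))
      for (j in seq_along(g$times))
        g$conc[[m]][[j]] <- g$conc[[m]][[j]] * (1 + f)
    g
  })
  o1 <- pk_objective(fx$true_theta, perturb(fx$data, 0.05), fx$cfg)
  o2 <- pk_objective(fx$true_theta, perturb(fx$data, 0.10), fx$cfg)
  # residuals double (0.05 -> 0.10): objective x4, modulo the weight
  # renormalization by the perturbed matrix means
  expect_equal(o2 / o1, 4 * (1.05 / 1.10)^2, tolerance = 1e-6)

  shuffled <- lapply(fx$data, function(g) {
    for (m in c("plasma", "ileum", "liver"))
      for (j in seq_along(g$times))
        g$conc[[m]][[j]] <- rev(g$conc[[m]][[j]])
    g
  })
  d2 <- perturb(fx$data, 0.05)
  s2 <- perturb(shuffled, 0.05)
  expect_equal(pk_objective(fx$true_theta, d2, fx$cfg),
               pk_objective(fx$true_theta, s2, fx$cfg))
})

test_that("calibration recovers the truth from scatter-free data", {
  fx <- make_estimation_fixture(seed = 4, cv = 0, max_evals = 1500)
  box <- chronopgp:::theta_box(fx$cfg)
  set.seed(99)
  th0 <- chronopgp:::theta_natural(
    fx$cfg, box$lower + runif(length(box$lower)) * (box$upper - box$lower))
  fit <- fit_group(fx$data, fx$cfg, seed = 1, theta0 = th0)
  rates <- setdiff(names(fx$true_theta), "renal_phase")
  expect_true(all(abs(fit$theta[rates] / fx$true_theta[rates] - 1) < 0.05))
  expect_lt(circular_distance(fit$theta["renal_phase"],
                              fx$true_theta[["renal_phase"]], 24), 0.5)
  # constraints respected at the optimum
  expect_gte(fit$theta[["renal_phase"]], 12)
  expect_lte(fit$theta[["renal_phase"]], 24)
  # restart incumbents never increase
  expect_true(all(diff(fit$history) <= 1e-12))
})

test_that("bounds excluding the truth give a boundary optimum", {
  truth <- reference_parameters()
  free <- data.frame(name = "ka", lower = truth$ka * 2, upper = truth$ka * 6,
                     transform = "log")
  cfg <- estimation_config(truth, free, max_evals = 400)
  des <- experiment_design(n_mice_per_time = 2)
  dat <- gen_pk_experiment(des, truth, noise_model(0, 0, 0), seed = 5)
  fit <- fit_group(dat, cfg, seed = 1)
  expect_equal(fit$theta[["ka"]], truth$ka * 2, tolerance = 0.01)
})

test_that("repeated runs from different seeds reach comparable optima", {
  fx <- make_estimation_fixture(seed = 6, cv = 0.1, max_evals = 800)
  f1 <- fit_group(fx$data, fx$cfg, seed = 11)
  f2 <- fit_group(fx$data, fx$cfg, seed = 22)
  expect_lt(abs(f1$objective - f2$objective) /
              max(f1$objective, f2$objective), 0.01)
})

test_that("virtual-dataset resampling is seeded and respects linking", {
  fx <- make_estimation_fixture(seed = 7, cv = 0.3)
  v1 <- chronopgp:::resample_virtual(fx$data, seed = 9, linked = TRUE)
  v2 <- chronopgp:::resample_virtual(fx$data, seed = 9, linked = TRUE)
  expect_identical(v1, v2)
  # linked mode: the picked mouse occupies the same slot in all matrices
  g <- fx$data[[1]]; vg <- v1[[1]]
  for (j in seq_along(g$times)) {
    hits <- vapply(c("plasma", "ileum", "liver"), function(m)
      match(vg$conc[[m]][[j]], g$conc[[m]][[j]]), integer(1))
    expect_equal(length(unique(hits)), 1L)
    expect_length(vg$conc$plasma[[j]], 1L)
  }
})

test_that("Monte-Carlo with a single dataset flags undefined SDs", {
  fx <- make_estimation_fixture(seed = 8, cv = 0, n_mice = 2,
                                max_evals = 200)
  base <- fit_group(fx$data, fx$cfg, seed = 1, theta0 = fx$true_theta)
  expect_warning(
    mc <- monte_carlo_fit(fx$data, fx$cfg, n_datasets = 1, seed = 1,
                          base_fit = base, sub_max_evals = 100),
    "undefined")
  expect_true(all(is.na(mc$mc$sd)))
})
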