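make_unit_spec <- function(n_total = 4000, seed = 1) {
  sensitivity_spec(
    data.frame(name = c("x1", "x2", "x3"), lower = 0, upper = 1,
               scale = "linear"),
    n_total = n_total, seed = seed)
}

test_that("Saltelli designs have the right shape, bounds and determinism", {
  fac <- data.frame(name = c("a", "b"), lower = c(0.1, 5),
                    upper = c(1, 50), scale = c("log", "linear"))
  spec <- sensitivity_spec(fac, n_total = 400, seed = 3)
  X <- saltelli_sample(spec)
  expect_equal(nrow(X), spec$N * 4)  # N*(d+2), d = 2
  expect_lte(nrow(X), 400)
  expect_true(all(X[, "a"] >= 0.1 & X[, "a"] <= 1))
  expect_true(all(X[, "b"] >= 5 & X[, "b"] <= 50))
  expect_identical(X, saltelli_sample(spec))
  expect_error(sensitivity_spec(fac, n_total = 100), "too small")
})

test_that("sampled marginals are uniform on their design scales", {
  fac <- data.frame(name = c("r", "p"), lower = c(0.01, 0),
                    upper = c(1, 24), scale = c("log", "linear"))
  spec <- sensitivity_spec(fac, n_total = 4000, seed = 5)
  X <- saltelli_sample(spec)
  A <- X[seq_len(spec$N), ]
  ks_log <- suppressWarnings(
    ks.test(log(A[, "r"]), "punif", log(0.01), log(1)))
  ks_lin <- suppressWarnings(ks.test(A[, "p"], "punif", 0, 24))
  expect_gt(ks_log$p.value, 0.01)
  expect_gt(ks_lin$p.value, 0.01)
})

test_that("total-order indices match the analytic additive decomposition", {
  spec <- make_unit_spec(n_total = 12000, seed = 2)
  X <- saltelli_sample(spec)
  cvec <- c(1, 2, 3)
  res <- sobol_total_order(drop(X %*% cvec), spec)
  expect_equal(res$indices$total_order, cvec^2 / sum(cvec^2),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_true(all(res$indices$total_order_sd > 0))
})

test_that("constant outputs give zero indices", {
  spec <- make_unit_spec()
  y <- rep(2.5, spec$N * 5)
  res <- sobol_total_order(y, spec)
  expect_equal(res$indices$total_order, rep(0, 3))
})

test_that("total-order dominates first-order on an interacting benchmark", {
  fac <- data.frame(name = c("x1", "x2", "x3"), lower = -pi, upper = pi,
                    scale = "linear")
  spec <- sensitivity_spec(fac, n_total = 12000, seed = 8)
  X <- saltelli_sample(spec)
  y <- sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
  res <- sobol_total_order(y, spec)
  expect_true(all(res$indices$total_order >=
                    res$indices$first_order - 0.05))
  # x3 acts only through interaction: first-order ~ 0, total-order > 0.1
  expect_lt(abs(res$indices$first_order[3]), 0.05)
  expect_gt(res$indices$total_order[3], 0.1)
})

test_that("failed evaluations are dropped up to 1% and rejected beyond", {
  spec <- make_unit_spec(n_total = 4000, seed = 4)
  X <- saltelli_sample(spec)
  y <- drop(X %*% c(1, 2, 3))
  y_few <- y; y_few[1] <- NA  # 1 of N base rows
  res <- sobol_total_order(y_few, spec)
  expect_equal(res$n_dropped, 1L)
  y_many <- y; y_many[seq_len(floor(spec$N * 0.05))] <- NA
  expect_error(sobol_total_order(y_many, spec), ">1%")
})

test_that("a single active model factor takes an index near 1", {
  ref <- reference_parameters()
  fac <- data.frame(name = c("renal_mesor", "u1", "u2"),
                    lower = c(ref$renal$mean_rate / 10, 0, 0),
                    upper = c(ref$renal$mean_rate * 10, 1, 1),
                    scale = c("log", "linear", "linear"))
  # the 100-fold log bounds give a heavily skewed output; the Jansen
  # estimator needs a few thousand base rows to settle
  spec <- sensitivity_spec(fac, n_total = 10000, seed = 6)
  X <- saltelli_sample(spec)
  # all parameters frozen except the renal mesor; u1/u2 are inert
  y <- vapply(seq_len(nrow(X)), function(r) {
    p <- set_pbpk_param(ref, "renal_mesor", X[r, 1])
    model_auc(simulate_pbpk(p, dose_event(zt_dose = 3),
                            times = seq(0, 8, 0.5), rtol = 1e-6,
                            atol = 1e-9), "plasma")
  }, numeric(1))
  res <- sobol_total_order(y, spec)
  expect_gt(res$indices$total_order[1], 0.95)
  expect_lt(max(res$indices$total_order[2:3]), 0.05)
})

test_that("the full model sensitivity run is deterministic given the seed", {
  spec <- sensitivity_spec(default_sensitivity_factors(), n_total = 1000,
                           seed = 12)
  r1 <- run_sensitivity(reference_parameters(), spec)
  r2 <- run_sensitivity(reference_parameters(), spec)
  expect_identical(r1$AUC_ileum_0_8$indices, r2$AUC_ileum_0_8$indices)
  expect_identical(names(r1), c("AUC_ileum_0_8", "AUC_liver_0_8"))
})
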