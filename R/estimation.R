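#' Destructive-sampling PK dataset for one experimental group
#'
#' Talinolol concentration measurements for one sex x feeding x dosing-ZT
#' group.  Sampling is destructive: each mouse is sacrificed at one time
#' point and contributes one concentration per matrix (plasma ug/mL, ileum
#' and liver ug/g).
#'
#' @param sex "F" or "M".
#' @param feeding "fed" or "fasted".
#' @param zt_dose dosing Zeitgeber time (study design: 3 or 15).
#' @param times sacrifice times in hours post-dose (default
#'   `c(0.5, 1, 2, 4, 6, 8)`).
#' @param conc named list with elements `plasma`, `ileum`, `liver`; each a
#'   list over `times` of per-mouse concentration vectors.  When mice are
#'   linked across matrices, the j-th entry at a time point refers to the
#'   same animal in all three matrices.
#' @return An object of class `pk_group_dataset`.
#' @export
pk_group_dataset <- function(sex, feeding, zt_dose, conc,
                             times = c(0.5, 1, 2, 4, 6, 8)) {
  stopifnot(is.list(conc), all(c("plasma", "ileum", "liver") %in% names(conc)))
  for (m in c("plasma", "ileum", "liver")) {
    if (length(conc[[m]]) != length(times))
      stop("matrix ", m, ": need one replicate vector per time point")
    if (any(lengths(conc[[m]]) < 1L))
      stop("matrix ", m, ": empty time point")
    v <- unlist(conc[[m]], use.names = FALSE)
    if (any(!is.finite(v)) || any(v < 0))
      stop("matrix ", m, ": concentrations must be finite and >= 0")
  }
  structure(list(sex = sex, feeding = feeding, zt_dose = zt_dose,
                 times = as.numeric(times), conc = conc),
            class = "pk_group_dataset")
}

#' @export
print.pk_group_dataset <- function(x, ...) {
  cat(sprintf("PK group: sex %s, %s, dosed at ZT%g; %d times, %d mice total\n",
              x$sex, x$feeding, x$zt_dose, length(x$times),
              sum(lengths(x$conc$plasma))))
  invisible(x)
}

#' Calibration configuration
#'
#' Defines the free parameters (bounds and transforms), the fixed
#' template containing everything not estimated (including rhythm shapes
#' fixed from protein cosinor fits for fed groups), and optimizer
#' settings.  Rates and mesors are log-transformed for optimization;
#' phase parameters stay linear and are boxed: clearance acrophases are
#' constrained to the nocturnal active phase ZT12-ZT24, and for fasted
#' groups P-gp amplitude upper bounds should be set to the fed-group
#' values (fasting dampens rhythms).
#'
#' @param template a [pbpk_parameters] object providing all fixed values.
#' @param free data.frame with columns `name`, `lower`, `upper`,
#'   `transform` ("log" or "identity").  Names follow
#'   `ka`, `k_ib`, `k_pl_li`, `k_li_pl`, or `<rate>_mesor`, `<rate>_amp`,
#'   `<rate>_phase` for `pgp_ileum`, `pgp_liver`, `renal`, `intestinal`
#'   (`_amp`/`_phase` address the first harmonic of that rate).
#' @param sigma0,max_evals,lambda CMA-ES settings per restart round.
#' @param restart_tol relative objective improvement below which the
#'   restart loop stops (default 1e-4).
#' @param max_restarts maximum restart rounds (default 10).
#' @param rtol,atol solver tolerances used inside the objective.
#' @return An object of class `estimation_config`.
#' @export
estimation_config <- function(template, free, sigma0 = 0.3,
                              max_evals = 1500, lambda = NULL,
                              restart_tol = 1e-4, max_restarts = 10,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(template, "pbpk_parameters"),
            is.data.frame(free),
            all(c("name", "lower", "upper", "transform") %in% names(free)),
            all(is.finite(free$lower)), all(is.finite(free$upper)),
            all(free$lower < free$upper),
            all(free$transform %in% c("log", "identity")))
  if (any(free$transform == "log" & free$lower <= 0))
    stop("log-transformed parameters need positive lower bounds")
  structure(list(template = template, free = free, sigma0 = sigma0,
                 max_evals = max_evals, lambda = lambda,
                 restart_tol = restart_tol, max_restarts = max_restarts,
                 rtol = rtol, atol = atol),
            class = "estimation_config")
}

#' Default free-parameter table
#'
#' Convenience table for the standard fed-group calibration: the four
#' transfer constants and the mesors of ileum/hepatic P-gp activity
#' (rhythm shapes fixed from protein data in the template), plus the
#' renal mesor and its acrophase boxed into ZT12-24.  Bounds are 10-fold
#' around the supplied reference values for rates, following the
#' convention used for the sensitivity bounds.
#'
#' @param ref a [pbpk_parameters] object giving reference magnitudes.
#' @return data.frame suitable for [estimation_config].
#' @export
default_free_table <- function(ref = reference_parameters()) {
  rate_row <- function(name, v)
    data.frame(name = name, lower = v / 10, upper = v * 10,
               transform = "log")
  rbind(
    rate_row("ka", ref$ka),
    rate_row("k_ib", ref$k_ib),
    rate_row("k_pl_li", ref$k_pl_li),
    rate_row("k_li_pl", ref$k_li_pl),
    rate_row("pgp_ileum_mesor", ref$pgp_ileum$mean_rate),
    rate_row("pgp_liver_mesor", ref$pgp_liver$mean_rate),
    rate_row("renal_mesor", ref$renal$mean_rate),
    data.frame(name = "renal_phase", lower = 12, upper = 24,
               transform = "identity"))
}

#' Set one named kinetic parameter on a parameter object
#'
#' Addresses transfer constants by name (`ka`, `k_ib`, `k_pl_li`,
#' `k_li_pl`) and circadian-rate fields as `<rate>_mesor`, `<rate>_amp`
#' or `<rate>_phase` (first harmonic) for `pgp_ileum`, `pgp_liver`,
#' `renal` and `intestinal`.  The modified circadian rate is revalidated.
#'
#' @param p a [pbpk_parameters] object.
#' @param name parameter name as above.
#' @param value new value (1/h for rates, fraction for amplitudes, hours
#'   for phases).
#' @return The modified [pbpk_parameters] object.
#' @export
set_pbpk_param <- function(p, name, value) {
  if (name %in% c("ka", "k_ib", "k_pl_li", "k_li_pl")) {
    p[[name]] <- value
    return(p)
  }
  m <- regmatches(name, regexec(
    "^(pgp_ileum|pgp_liver|renal|intestinal)_(mesor|amp|phase)$", name))[[1]]
  if (length(m) == 0) stop("unknown parameter name: ", name)
  rate <- p[[m[2]]]
  if (m[3] == "mesor") {
    rate$mean_rate <- value
  } else {
    if (length(rate$rel_amplitudes) < 1L)
      stop(name, ": rate has no harmonic to address; give the template one")
    if (m[3] == "amp") rate$rel_amplitudes[1] <- value
    else rate$acrophases[1] <- value %% rate$periods[1]
  }
  # revalidate (sum of relative amplitudes <= 1 etc.)
  p[[m[2]]] <- circadian_rate(rate$mean_rate, rate$rel_amplitudes,
                              rate$periods, rate$acrophases)
  p
}

#' Build a parameter object from a free-parameter vector
#'
#' @param cfg an [estimation_config].
#' @param theta named or positional vector in natural units, parallel to
#'   `cfg$free`.
#' @return A [pbpk_parameters] object.
#' @export
apply_theta <- function(cfg, theta) {
  p <- cfg$template
  for (i in seq_len(nrow(cfg$free)))
    p <- set_pbpk_param(p, cfg$free$name[i], theta[[i]])
  p
}

# transformed-space box for the optimizer
theta_box <- function(cfg) {
  lo <- ifelse(cfg$free$transform == "log", log(cfg$free$lower),
               cfg$free$lower)
  hi <- ifelse(cfg$free$transform == "log", log(cfg$free$upper),
               cfg$free$upper)
  list(lower = lo, upper = hi)
}
theta_natural <- function(cfg, theta_t) {
  v <- ifelse(cfg$free$transform == "log", exp(theta_t), theta_t)
  stats::setNames(v, cfg$free$name)
}

#' Weighted least-squares objective
#'
#' Sum over matrices, dosing-ZT groups, time points and mice of
#' `w_m * (C_model - C_obs)^2`, where the matrix weight
#' `w_m = 1 / mean(C_obs in matrix m)^2` puts plasma, ileum and liver
#' residuals on a comparable (relative) scale despite their roughly
#' hundredfold concentration differences.  Simulation failures and
#' invalid parameter combinations return a large penalty.
#'
#' @param theta free-parameter vector in natural units.
#' @param data_pair list of [pk_group_dataset] (typically dosing at ZT3
#'   and ZT15) sharing one parameter set.
#' @param cfg an [estimation_config].
#' @return Non-negative scalar.
#' @export
pk_objective <- function(theta, data_pair, cfg) {
  p <- tryCatch(apply_theta(cfg, theta), error = function(e) NULL)
  if (is.null(p)) return(1e12)
  w <- matrix_weights(data_pair)
  total <- 0
  for (grp in data_pair) {
    sim <- tryCatch(
      simulate_pbpk(p, dose_event(zt_dose = grp$zt_dose),
                    times = c(0, grp$times),
                    rtol = cfg$rtol, atol = cfg$atol),
      error = function(e) NULL)
    if (is.null(sim)) return(1e12)
    for (m in c("plasma", "ileum", "liver")) {
      pred <- sim$concentrations[match(grp$times, sim$t), m]
      for (j in seq_along(grp$times)) {
        obs <- grp$conc[[m]][[j]]
        total <- total + w[[m]] * sum((pred[j] - obs)^2)
      }
    }
  }
  total
}

matrix_weights <- function(data_pair) {
  out <- list()
  for (m in c("plasma", "ileum", "liver")) {
    v <- unlist(lapply(data_pair, function(g)
      unlist(g$conc[[m]], use.names = FALSE)), use.names = FALSE)
    mu <- mean(v)
    out[[m]] <- if (mu > 0) 1 / mu^2 else 0
  }
  out
}

#' Calibrate a group with CMA-ES and iterative restarts
#'
#' Minimizes [pk_objective] with [cma_es], then restarts from the
#' incumbent (with a reduced step size) until the relative improvement
#' between consecutive rounds falls below `cfg$restart_tol` or
#' `cfg$max_restarts` rounds have run.
#'
#' @param data_pair list of [pk_group_dataset] fitted jointly.
#' @param cfg an [estimation_config].
#' @param seed integer seed for the optimizer.
#' @param theta0 optional start (natural units; default: box midpoint on
#'   the transformed scale).
#' @return An object of class `pbpk_fit`: `best_params`
#'   ([pbpk_parameters]), `theta` (named, natural units), `objective`,
#'   `history` (incumbent objective per round), `evals`.
#' @export
fit_group <- function(data_pair, cfg, seed = 1L, theta0 = NULL) {
  stopifnot(inherits(cfg, "estimation_config"))
  if (inherits(data_pair, "pk_group_dataset")) data_pair <- list(data_pair)
  box <- theta_box(cfg)
  obj_t <- function(th_t) pk_objective(theta_natural(cfg, th_t),
                                       data_pair, cfg)
  x <- if (is.null(theta0)) {
    (box$lower + box$upper) / 2
  } else {
    ifelse(cfg$free$transform == "log", log(theta0), theta0)
  }
  f_inc <- obj_t(x)
  history <- numeric(0)
  evals <- 1L
  sigma <- cfg$sigma0
  for (round in seq_len(cfg$max_restarts)) {
    res <- cma_es(obj_t, x, box$lower, box$upper, sigma0 = sigma,
                  lambda = cfg$lambda, max_evals = cfg$max_evals,
                  seed = as.integer(seed) + round - 1L)
    evals <- evals + res$evals
    if (res$value < f_inc) {
      improved <- (f_inc - res$value) / max(abs(f_inc), 1e-30)
      x <- res$par  # already in transformed space
      f_inc <- res$value
    } else improved <- 0
    history <- c(history, f_inc)
    sigma <- max(cfg$sigma0 / 3, sigma * 0.5)
    if (round > 1 && improved < cfg$restart_tol) break
  }
  theta <- theta_natural(cfg, x)
  structure(list(best_params = apply_theta(cfg, theta), theta = theta,
                 objective = f_inc, history = history, evals = evals,
                 cfg = cfg),
            class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("PBPK fit: objective %.6g after %d rounds (%d evaluations)\n",
              x$objective, length(x$history), x$evals))
  print(round(x$theta, 5))
  invisible(x)
}

#' Monte-Carlo resampling of virtual datasets
#'
#' Quantifies parameter uncertainty from inter-animal variability:
#' repeatedly builds a virtual dataset by randomly picking one mouse per
#' time point (per matrix, or linked across matrices as destructive
#' sampling implies - default), refits each virtual dataset starting from
#' the averaged-data incumbent, and reports per-parameter means and
#' standard deviations.
#'
#' @param data_pair list of [pk_group_dataset].
#' @param cfg an [estimation_config].
#' @param n_datasets number of virtual datasets (study value 200; reduce
#'   for quick checks).
#' @param seed integer seed.
#' @param linked logical; pick the same mouse index across the three
#'   matrices at each time point (default TRUE).
#' @param base_fit optional `pbpk_fit` on the full data used as the
#'   common starting point (computed if missing).
#' @param sub_max_evals CMA-ES budget per virtual dataset (default:
#'   `cfg$max_evals`).
#' @return A `pbpk_fit` for the full data, augmented with `mc`: a list
#'   with `params` (n_datasets x d matrix), `mean`, `sd`, `n_failed`.
#' @export
monte_carlo_fit <- function(data_pair, cfg, n_datasets = 200, seed = 1L,
                            linked = TRUE, base_fit = NULL,
                            sub_max_evals = cfg$max_evals) {
  if (inherits(data_pair, "pk_group_dataset")) data_pair <- list(data_pair)
  if (n_datasets < 2)
    warning("n_datasets < 2: Monte-Carlo SDs undefined (reported as NA)")
  if (is.null(base_fit)) base_fit <- fit_group(data_pair, cfg, seed = seed)

  sub_cfg <- cfg
  sub_cfg$max_evals <- sub_max_evals
  sub_cfg$max_restarts <- min(cfg$max_restarts, 3L)
  sub_cfg$sigma0 <- cfg$sigma0 / 3  # local refinement around the incumbent

  d <- nrow(cfg$free)
  params <- matrix(NA_real_, nrow = n_datasets, ncol = d,
                   dimnames = list(NULL, cfg$free$name))
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    vd <- resample_virtual(data_pair, seed = as.integer(seed) + 1000L + i,
                           linked = linked)
    fit_i <- tryCatch(
      fit_group(vd, sub_cfg, seed = as.integer(seed) + 2000L + i,
                theta0 = base_fit$theta),
      error = function(e) NULL)
    if (is.null(fit_i)) { n_failed <- n_failed + 1L; next }
    params[i, ] <- fit_i$theta
  }
  ok <- stats::complete.cases(params)
  out <- base_fit
  out$mc <- list(
    params = params[ok, , drop = FALSE],
    mean = colMeans(params[ok, , drop = FALSE]),
    sd = if (sum(ok) >= 2) apply(params[ok, , drop = FALSE], 2, stats::sd)
         else stats::setNames(rep(NA_real_, d), cfg$free$name),
    n_datasets = n_datasets, n_failed = n_failed)
  out
}

# One virtual dataset: one mouse per time point (per matrix, or linked).
resample_virtual <- function(data_pair, seed, linked = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(data_pair, function(grp) {
    conc <- grp$conc
    for (j in seq_along(grp$times)) {
      if (linked) {
        idx <- sample.int(length(conc$plasma[[j]]), 1)
        for (m in c("plasma", "ileum", "liver"))
          conc[[m]][[j]] <- conc[[m]][[j]][idx]
      } else {
        for (m in c("plasma", "ileum", "liver")) {
          idx <- sample.int(length(conc[[m]][[j]]), 1)
          conc[[m]][[j]] <- conc[[m]][[j]][idx]
        }
      }
    }
    pk_group_dataset(grp$sex, grp$feeding, grp$zt_dose, conc,
                     times = grp$times)
  })
}
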