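#' Timed replicate measurements across the circadian cycle
#'
#' Container for destructive-sampling circadian designs: at each Zeitgeber
#' time (ZT, hours after light onset) a group of animals is sacrificed and
#' one measurement per animal is recorded.
#'
#' @param zt_hours numeric vector of sampling times in hours, each in
#'   \[0, 24); at least 3 distinct times are required.
#' @param values_per_zt list of numeric vectors, one per element of
#'   `zt_hours`, holding the replicate measurements at that time.
#' @param label free-text description (tissue/analyte/sex/feeding).
#'
#' @return An object of class `timed_replicates`.
#' @export
timed_replicates <- function(zt_hours, values_per_zt, label = "") {
  if (!is.numeric(zt_hours) || length(zt_hours) < 3L)
    stop("need at least 3 sampling times")
  if (any(zt_hours < 0 | zt_hours >= 24))
    stop("all Zeitgeber times must lie in [0, 24)")
  if (length(unique(zt_hours)) < 3L)
    stop("need at least 3 distinct sampling times")
  if (!is.list(values_per_zt) || length(values_per_zt) != length(zt_hours))
    stop("values_per_zt must be a list parallel to zt_hours")
  n_rep <- vapply(values_per_zt, length, integer(1))
  if (any(n_rep < 1L)) stop("every sampling time needs at least 1 replicate")
  vals <- unlist(values_per_zt, use.names = FALSE)
  if (!all(is.finite(vals))) stop("all values must be finite")
  structure(
    list(zt_hours = as.numeric(zt_hours),
         values_per_zt = lapply(values_per_zt, as.numeric),
         label = as.character(label)[1]),
    class = "timed_replicates")
}

#' @export
print.timed_replicates <- function(x, ...) {
  cat("Timed replicates:", if (nzchar(x$label)) x$label else "<unlabelled>",
      "\n  ", length(x$zt_hours), "sampling times,",
      sum(lengths(x$values_per_zt)), "observations\n")
  invisible(x)
}

# Flatten a timed_replicates object to (t, y) observation pairs.
tr_observations <- function(data) {
  t <- rep(data$zt_hours, lengths(data$values_per_zt))
  y <- unlist(data$values_per_zt, use.names = FALSE)
  list(t = t, y = y)
}

#' Multi-harmonic cosinor fit
#'
#' Least-squares fit of a rhythm-adjusted mean (mesor) plus cosine
#' components at fixed candidate periods, by default the fundamental 24 h
#' period and its first two harmonics (12 h and 8 h).  The model is
#' \deqn{y(t) = M + \sum_k a_k \cos(2\pi t/T_k) + b_k \sin(2\pi t/T_k)}
#' fitted by ordinary least squares over all replicate observations.  Each
#' component is reported as an amplitude (half the peak-trough difference)
#' and an acrophase (time of the component maximum within one period).
#' Per-component significance is the classical zero-amplitude test: a
#' partial F-test of the sine/cosine coefficient pair against the model
#' with that pair removed.
#'
#' @param data a [timed_replicates] object.
#' @param periods candidate periods in hours (default `c(24, 12, 8)`).
#'
#' @return An object of class `cosinor_fit`: a list with `mesor`,
#'   `components` (data.frame with period, amplitude, acrophase, p_value),
#'   `residual_ss`, `n_obs`, `coef` and the fitted `lm` object.
#' @export
fit_cosinor <- function(data, periods = c(24, 12, 8)) {
  stopifnot(inherits(data, "timed_replicates"))
  if (any(periods <= 0)) stop("periods must be positive")
  obs <- tr_observations(data)
  n_distinct <- length(unique(data$zt_hours))
  if (n_distinct < 1L + 2L * length(periods))
    stop(sprintf(
      "under-determined design: %d distinct times for %d coefficients",
      n_distinct, 1L + 2L * length(periods)))

  X <- cosinor_basis(obs$t, periods)
  df <- data.frame(y = obs$y, X)
  full <- stats::lm(y ~ . - 1, data = df)  # basis already has intercept
  rss_full <- sum(stats::resid(full)^2)
  df_res <- full$df.residual

  comps <- lapply(seq_along(periods), function(k) {
    a <- stats::coef(full)[[paste0("c", k)]]
    b <- stats::coef(full)[[paste0("s", k)]]
    amp <- sqrt(a^2 + b^2)
    # a*cos(wt)+b*sin(wt) is maximal at wt = atan2(b, a)
    acro <- (atan2(b, a) * periods[k] / (2 * pi)) %% periods[k]
    # zero-amplitude partial F-test: drop this component's coefficient pair
    keep <- setdiff(colnames(X), c(paste0("c", k), paste0("s", k)))
    red <- stats::lm(y ~ . - 1, data = df[, c("y", keep), drop = FALSE])
    rss_red <- sum(stats::resid(red)^2)
    if (rss_full < .Machine$double.eps * max(1, rss_red)) {
      # noise-free data: F-test degenerate; component significant iff it
      # explains variance
      p <- if (rss_red - rss_full > 1e-12 * max(1, rss_red)) 0 else 1
    } else {
      fstat <- ((rss_red - rss_full) / 2) / (rss_full / df_res)
      p <- stats::pf(fstat, 2, df_res, lower.tail = FALSE)
    }
    data.frame(period = periods[k], amplitude = amp, acrophase = acro,
               p_value = p)
  })
  comps <- do.call(rbind, comps)

  structure(
    list(mesor = unname(stats::coef(full)[["m"]]),
         components = comps,
         residual_ss = rss_full,
         n_obs = length(obs$y),
         coef = stats::coef(full),
         periods = periods,
         label = data$label),
    class = "cosinor_fit")
}

cosinor_basis <- function(t, periods) {
  X <- matrix(1, nrow = length(t), ncol = 1 + 2 * length(periods))
  cn <- "m"
  for (k in seq_along(periods)) {
    w <- 2 * pi / periods[k]
    X[, 2 * k]     <- cos(w * t)
    X[, 2 * k + 1] <- sin(w * t)
    cn <- c(cn, paste0("c", k), paste0("s", k))
  }
  colnames(X) <- cn
  X
}

#' Construct a cosinor fit directly from known rhythm parameters
#'
#' Builds a `cosinor_fit` object from mesor/amplitude/acrophase values
#' without fitting, e.g. to specify the ground truth of a simulated rhythm.
#'
#' @param mesor rhythm-adjusted mean.
#' @param periods,amplitudes,acrophases parallel numeric vectors (hours,
#'   data units, hours); may be empty for an arrhythmic signal.
#' @return A `cosinor_fit` object (p-values `NA`).
#' @export
cosinor_truth <- function(mesor, periods = numeric(), amplitudes = numeric(),
                          acrophases = numeric()) {
  stopifnot(length(periods) == length(amplitudes),
            length(periods) == length(acrophases),
            all(amplitudes >= 0), all(periods > 0))
  comps <- data.frame(period = as.numeric(periods),
                      amplitude = as.numeric(amplitudes),
                      acrophase = as.numeric(acrophases) %% ifelse(
                        length(periods) > 0, periods, 1),
                      p_value = rep(NA_real_, length(periods)))
  structure(list(mesor = mesor, components = comps, residual_ss = 0,
                 n_obs = 0L, coef = NULL, periods = as.numeric(periods),
                 label = "truth"),
            class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit", if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  mesor: %.4g   residual SS: %.4g   n: %d\n",
              x$mesor, x$residual_ss, x$n_obs))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Evaluate a cosinor fit at arbitrary times
#'
#' @param fit a `cosinor_fit`.
#' @param t times in hours (ZT).
#' @return Fitted values `mesor + sum_k A_k cos(2*pi*(t - phi_k)/T_k)`.
#' @export
predict_cosinor <- function(fit, t) {
  stopifnot(inherits(fit, "cosinor_fit"))
  y <- rep(fit$mesor, length(t))
  cmp <- fit$components
  if (nrow(cmp) > 0) {
    for (k in seq_len(nrow(cmp))) {
      y <- y + cmp$amplitude[k] *
        cos(2 * pi * (t - cmp$acrophase[k]) / cmp$period[k])
    }
  }
  y
}

#' Remove a linear trend and normalize a series to mean 1
#'
#' Fits an ordinary least-squares line to `y` over `t`, keeps the
#' residuals, adds back the pre-detrend mean, and divides by that mean so
#' the returned series has mean exactly 1 while relative (fractional)
#' oscillation amplitudes are preserved.
#'
#' @param t sampling times (hours).
#' @param y measurements; must be positive on average.
#' @return Numeric vector of the same length with mean 1.
#' @export
detrend_normalize <- function(t, y) {
  stopifnot(length(t) == length(y), length(y) >= 3, all(is.finite(y)))
  m <- mean(y)
  if (m <= 0) stop("series mean must be positive to normalize")
  res <- stats::resid(stats::lm(y ~ t))
  out <- (res + m) / m
  if (mean(out) <= 0) stop("non-positive mean after detrending")
  out
}

#' Fit a damped cosine to a detrended, normalized series
#'
#' Fits \deqn{y(t) = 1 + A e^{-\lambda t} \cos(2\pi (t - \phi)/T)} by
#' bounded nonlinear least squares (Levenberg-Marquardt), with multi-start
#' initialization over a grid of candidate periods (16-32 h by default) and
#' four phase offsets per period, plus seed-controlled jitter.  Intended
#' for dense long recordings such as multi-day bioluminescence traces
#' sampled every few minutes.
#'
#' @param t times in hours.
#' @param y_norm series normalized to mean 1 (see [detrend_normalize]).
#' @param seed integer seed for the initialization jitter.
#' @param period_grid candidate periods for multi-start (hours).
#' @param period_bounds lower/upper bounds on the period (hours).
#'
#' @return An object of class `damped_cosine_fit` with `period` (h),
#'   `relative_amplitude` (fraction of the mesor, which is 1 after
#'   normalization), `acrophase` (h, in \[0, period)), `damping_rate`
#'   (1/h), `residual_ss`, and a logical `degenerate` flag raised when the
#'   fitted amplitude is negligible (period/phase then unidentifiable).
#' @export
fit_damped_cosine <- function(t, y_norm, seed = 1L,
                              period_grid = seq(16, 32, by = 2),
                              period_bounds = c(12, 48)) {
  stopifnot(length(t) == length(y_norm), length(t) >= 8)
  if (diff(range(t)) < 2 * min(period_grid))
    warning("series spans fewer than two candidate periods; fit may be unstable")

  resid_fun <- function(p) {
    1 + p[1] * exp(-p[2] * t) * cos(2 * pi * (t - p[3]) / p[4]) - y_norm
  }
  lower <- c(0,   0,    -48, period_bounds[1])
  upper <- c(10,  1,     96, period_bounds[2])

  amp0 <- max(2 * stats::sd(y_norm), 1e-3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  best <- NULL
  starts <- list()
  for (T0 in period_grid) {
    for (ph in c(0, T0 / 4, T0 / 2, 3 * T0 / 4)) {
      p0 <- c(amp0 * stats::runif(1, 0.8, 1.2), 0.005, ph, T0)
      starts[[length(starts) + 1L]] <- p0
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ss <- sum(fit$fvec^2)
      if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
    }
  }
  if (is.null(best))
    stop("damped-cosine fit failed to converge from any of ",
         length(starts), " starts")

  p <- best$fit$par
  A <- p[1]; lam <- p[2]; phi <- p[3]; Tper <- p[4]
  degenerate <- A < 1e-3  # < 0.1% of mesor: rhythm indistinguishable from flat
  structure(
    list(period = Tper,
         relative_amplitude = A,
         acrophase = if (degenerate) NA_real_ else phi %% Tper,
         damping_rate = lam,
         residual_ss = best$ss,
         degenerate = degenerate,
         n_starts = length(starts),
         start_objectives = vapply(starts,
                                   function(s) sum(resid_fun(s)^2),
                                   numeric(1))),
    class = "damped_cosine_fit")
}

#' @export
print.damped_cosine_fit <- function(x, ...) {
  cat(sprintf(paste0("Damped cosine fit: period %.3f h, relative amplitude ",
                     "%.3f,\n  acrophase %.3f h, damping %.5f 1/h, ",
                     "residual SS %.4g%s\n"),
              x$period, x$relative_amplitude, x$acrophase, x$damping_rate,
              x$residual_ss, if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Circular distance between two phases
#'
#' @param a,b phases in hours.
#' @param period period in hours (default 24).
#' @return `min(|a-b| mod T, T - |a-b| mod T)`.
#' @export
circular_distance <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
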