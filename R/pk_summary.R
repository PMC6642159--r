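#' Trapezoidal AUC over the first hours of exposure
#'
#' Area under a sparse concentration-time curve by the trapezoidal rule.
#' For an oral dose the concentration is zero at the moment of dosing, so
#' a (t = 0, C = 0) anchor is prepended by default when the first
#' observation is later than 0.
#'
#' @param times strictly increasing observation times (h).
#' @param conc concentrations at `times`.
#' @param anchor_zero prepend a zero-concentration point at t = 0
#'   (default TRUE).
#' @return AUC in concentration x hours.
#' @export
trapezoid_auc <- function(times, conc, anchor_zero = TRUE) {
  stopifnot(length(times) == length(conc))
  if (anchor_zero && times[1] > 0) {
    times <- c(0, times)
    conc <- c(0, conc)
  }
  if (length(times) < 2) stop("need at least 2 points for an AUC")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  trapz(times, conc)
}

#' Combinatorial curve construction from destructive sampling
#'
#' Destructive sampling yields independent groups of mice at each time
#' point, not longitudinal curves.  Complete time-concentration profiles
#' are therefore assembled by combining one mouse per time point.  All
#' combinations are enumerated when their number does not exceed `cap`
#' (4-5 mice at 6 time points gives 4^6 = 4096 up to 5^6 = 15,625
#' curves); above the cap, `cap` seeded random combinations are drawn.
#'
#' @param group a [pk_group_dataset].
#' @param matrix "plasma", "ileum" or "liver".
#' @param cap maximum number of curves (default 50000).
#' @param seed integer seed for capped random sampling.
#' @return List with `times` and `curves`, an `n_curves x n_times` matrix
#'   (one row per assembled profile), plus `enumerated` (logical).
#' @export
combinatorial_curves <- function(group, matrix = c("plasma", "ileum", "liver"),
                                 cap = 50000, seed = 1L) {
  stopifnot(inherits(group, "pk_group_dataset"))
  matrix <- match.arg(matrix)
  reps <- group$conc[[matrix]]
  n_t <- lengths(reps)
  if (any(n_t < 1L)) stop("empty time point in matrix ", matrix)
  n_comb <- prod(n_t)
  if (n_comb <= cap) {
    idx <- as.matrix(expand.grid(lapply(n_t, seq_len)))
    enumerated <- TRUE
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    idx <- vapply(n_t, function(n) sample.int(n, cap, replace = TRUE),
                  integer(cap))
    enumerated <- FALSE
  }
  curves <- vapply(seq_along(reps),
                   function(j) reps[[j]][idx[, j]],
                   numeric(nrow(idx)))
  if (!is.matrix(curves)) curves <- matrix(curves, nrow = 1)
  list(times = group$times, curves = curves, enumerated = enumerated)
}

#' Combinatorial AUC and Cmax summary
#'
#' Computes per-curve AUC over \[0, 8\] h (trapezoidal, zero-anchored at
#' t = 0 by default) and Cmax (maximum over observed time points, no
#' interpolation) across all combinatorial curves, and reports their
#' means and standard deviations.
#'
#' @param group a [pk_group_dataset].
#' @param matrix "plasma", "ileum" or "liver".
#' @param cap,seed passed to [combinatorial_curves].
#' @param anchor_zero passed to [trapezoid_auc].
#' @return An object of class `pk_summary`: group id fields, `n_curves`,
#'   `auc_mean`, `auc_sd`, `cmax_mean`, `cmax_sd`, and the per-curve
#'   values (`auc`, `cmax`).
#' @export
auc_cmax_stats <- function(group, matrix = c("plasma", "ileum", "liver"),
                           cap = 50000, seed = 1L, anchor_zero = TRUE) {
  matrix <- match.arg(matrix)
  cc <- combinatorial_curves(group, matrix, cap = cap, seed = seed)
  auc <- apply(cc$curves, 1, function(y)
    trapezoid_auc(cc$times, y, anchor_zero = anchor_zero))
  cmax <- apply(cc$curves, 1, max)
  structure(list(
    sex = group$sex, feeding = group$feeding, zt_dose = group$zt_dose,
    matrix = matrix, n_curves = nrow(cc$curves),
    enumerated = cc$enumerated,
    auc_mean = mean(auc), auc_sd = stats::sd(auc),
    cmax_mean = mean(cmax), cmax_sd = stats::sd(cmax),
    auc = auc, cmax = cmax),
    class = "pk_summary")
}

#' @export
print.pk_summary <- function(x, ...) {
  cat(sprintf(paste0("PK summary (%s, %s, ZT%g, %s): %d curves%s\n",
                     "  AUC0-8h %.4g +/- %.4g, Cmax %.4g +/- %.4g\n"),
              x$sex, x$feeding, x$zt_dose, x$matrix, x$n_curves,
              if (x$enumerated) " (full enumeration)" else " (capped sample)",
              x$auc_mean, x$auc_sd, x$cmax_mean, x$cmax_sd))
  invisible(x)
}
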