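#' Experimental design of the three circadian studies
#'
#' Holds the sampling layouts the generators emulate: destructive
#' circadian expression sampling (every 3 h over 24 h, 5 animals per ZT),
#' the talinolol PK study (sacrifice at 0.5, 1, 2, 4, 6, 8 h post-dose,
#' 4-5 mice per time, dosing at ZT3 and ZT15), and multi-day
#' bioluminescence recording (10-min sampling for up to 6 days).
#'
#' @param zts expression sampling ZTs (h).
#' @param n_per_zt animals per expression ZT.
#' @param pk_times PK sacrifice times (h post-dose).
#' @param n_mice_per_time mice per PK time point (4 or 5).
#' @param dose_zts dosing ZTs.
#' @param biolum_duration_h recording length (h).
#' @param biolum_dt_min sampling interval (min).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(zts = seq(0, 21, by = 3), n_per_zt = 5,
                              pk_times = c(0.5, 1, 2, 4, 6, 8),
                              n_mice_per_time = 5, dose_zts = c(3, 15),
                              biolum_duration_h = 144, biolum_dt_min = 10) {
  stopifnot(all(zts >= 0 & zts < 24), n_per_zt >= 1,
            all(pk_times > 0), n_mice_per_time >= 1,
            all(dose_zts >= 0 & dose_zts < 24),
            biolum_duration_h > 0, biolum_dt_min > 0)
  structure(list(zts = zts, n_per_zt = n_per_zt, pk_times = pk_times,
                 n_mice_per_time = n_mice_per_time, dose_zts = dose_zts,
                 biolum_duration_h = biolum_duration_h,
                 biolum_dt_min = biolum_dt_min),
            class = "experiment_design")
}

#' Noise model for the synthetic generators
#'
#' @param expression_cv lognormal coefficient of variation of each
#'   expression measurement (default 0.20).
#' @param pk_inter_animal_cv lognormal CV of each mouse's rate-parameter
#'   multiplier, shared across matrices so a mouse's plasma, ileum and
#'   liver values are internally consistent (default 0.20).
#' @param pk_assay_cv proportional Gaussian assay CV (default 0.075,
#'   within the 2-10\% HPLC reproducibility range).
#' @param lod_ug_mL assay limit of determination (default 0.05 ug/mL,
#'   i.e. 50 ng/mL); values below it are floored and flagged censored.
#' @param biolum_sd additive Gaussian noise on bioluminescence counts.
#' @param biolum_trend_slope linear drift in counts per hour.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(expression_cv = 0.20, pk_inter_animal_cv = 0.20,
                        pk_assay_cv = 0.075, lod_ug_mL = 0.05,
                        biolum_sd = 0, biolum_trend_slope = 0) {
  stopifnot(expression_cv >= 0, pk_inter_animal_cv >= 0, pk_assay_cv >= 0,
            lod_ug_mL >= 0, biolum_sd >= 0)
  structure(list(expression_cv = expression_cv,
                 pk_inter_animal_cv = pk_inter_animal_cv,
                 pk_assay_cv = pk_assay_cv, lod_ug_mL = lod_ug_mL,
                 biolum_sd = biolum_sd,
                 biolum_trend_slope = biolum_trend_slope),
            class = "noise_model")
}

# lognormal multiplier with unit mean and given CV
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a circadian expression dataset
#'
#' Draws `n_per_zt` replicate measurements at each design ZT from a known
#' cosinor rhythm with multiplicative lognormal noise.
#'
#' @param design an [experiment_design].
#' @param fit a `cosinor_fit` (e.g. from [cosinor_truth]) giving the true
#'   rhythm.
#' @param noise a [noise_model] (uses `expression_cv`).
#' @param seed integer seed.
#' @param label label carried by the returned object.
#' @return A [timed_replicates] object.
#' @export
gen_expression <- function(design, fit, noise = noise_model(), seed = 1L,
                           label = "synthetic expression") {
  stopifnot(inherits(design, "experiment_design"),
            inherits(fit, "cosinor_fit"), inherits(noise, "noise_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  vals <- lapply(design$zts, function(zt) {
    predict_cosinor(fit, zt) * rlnorm_cv(design$n_per_zt,
                                         noise$expression_cv)
  })
  timed_replicates(design$zts, vals, label = label)
}

#' Generate a two-dosing-time talinolol PK experiment
#'
#' Simulates a destructive-sampling PK study from known whole-body model
#' parameters: each virtual mouse receives its own lognormally perturbed
#' rate parameters (one multiplier per kinetic rate, shared across
#' matrices), is simulated forward from its group's dosing ZT, and is
#' "sacrificed" at one design time where its plasma, ileum and liver
#' concentrations are recorded with proportional assay noise.
#' Concentrations below the limit of determination are floored at it and
#' flagged.
#'
#' @param design an [experiment_design].
#' @param p true [pbpk_parameters].
#' @param noise a [noise_model].
#' @param seed integer seed.
#' @param sex,feeding group labels carried into the datasets.
#' @param dose_mg_per_kg oral dose (default 100, the study's gavage dose).
#' @return List of [pk_group_dataset], one per dosing ZT in
#'   `design$dose_zts`; each carries an attribute `censored` mirroring
#'   `conc` with logical flags.
#' @export
gen_pk_experiment <- function(design, p, noise = noise_model(), seed = 1L,
                              sex = "F", feeding = "fed",
                              dose_mg_per_kg = 100) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(p, "pbpk_parameters"), inherits(noise, "noise_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  rate_names <- c("ka", "k_ib", "k_pl_li", "k_li_pl")
  mesor_names <- c("pgp_ileum", "pgp_liver", "renal", "intestinal")
  lapply(design$dose_zts, function(zt) {
    conc <- list(plasma = list(), ileum = list(), liver = list())
    cens <- list(plasma = list(), ileum = list(), liver = list())
    for (j in seq_along(design$pk_times)) {
      tj <- design$pk_times[j]
      vals <- list(plasma = numeric(0), ileum = numeric(0),
                   liver = numeric(0))
      flag <- list(plasma = logical(0), ileum = logical(0),
                   liver = logical(0))
      for (mouse in seq_len(design$n_mice_per_time)) {
        pm <- p
        mult <- rlnorm_cv(length(rate_names) + length(mesor_names),
                          noise$pk_inter_animal_cv)
        for (i in seq_along(rate_names))
          pm[[rate_names[i]]] <- pm[[rate_names[i]]] * mult[i]
        for (i in seq_along(mesor_names))
          pm[[mesor_names[i]]]$mean_rate <-
            pm[[mesor_names[i]]]$mean_rate *
            mult[length(rate_names) + i]
        sim <- simulate_pbpk(pm, dose_event(dose_mg_per_kg, zt_dose = zt),
                             times = c(0, tj))
        for (m in c("plasma", "ileum", "liver")) {
          v <- sim$concentrations[2, m] *
            (1 + stats::rnorm(1, 0, noise$pk_assay_cv))
          v <- max(v, 0)
          below <- v < noise$lod_ug_mL
          vals[[m]] <- c(vals[[m]], if (below) noise$lod_ug_mL else v)
          flag[[m]] <- c(flag[[m]], below)
        }
      }
      for (m in c("plasma", "ileum", "liver")) {
        conc[[m]][[j]] <- vals[[m]]
        cens[[m]][[j]] <- flag[[m]]
      }
    }
    out <- pk_group_dataset(sex, feeding, zt, conc,
                            times = design$pk_times)
    attr(out, "censored") <- cens
    out
  })
}

#' Generate a long bioluminescence recording
#'
#' Dense photon-count series from a known damped-cosine rhythm:
#' `y(t) = baseline * (1 + A exp(-lambda t) cos(2 pi (t - phi)/T))
#'  + trend_slope * t + N(0, sd)`.
#'
#' @param design an [experiment_design] (uses duration and sampling
#'   interval).
#' @param period,rel_amplitude,acrophase,damping_rate true rhythm
#'   parameters (h, fraction of baseline, h, 1/h).
#' @param baseline mean count level (default 1000).
#' @param noise a [noise_model] (uses `biolum_sd`,
#'   `biolum_trend_slope`).
#' @param seed integer seed.
#' @return data.frame with columns `t_h`, `counts`.
#' @export
gen_bioluminescence <- function(design, period, rel_amplitude, acrophase,
                                damping_rate, baseline = 1000,
                                noise = noise_model(), seed = 1L) {
  stopifnot(inherits(design, "experiment_design"), period > 0,
            rel_amplitude >= 0, damping_rate >= 0, baseline > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- round(design$biolum_duration_h * 60 / design$biolum_dt_min)
  t <- (seq_len(n) - 1) * design$biolum_dt_min / 60
  y <- baseline * (1 + rel_amplitude * exp(-damping_rate * t) *
                     cos(2 * pi * (t - acrophase) / period)) +
    noise$biolum_trend_slope * t +
    stats::rnorm(n, 0, noise$biolum_sd)
  data.frame(t_h = t, counts = y)
}
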