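# Shared fixture builders (all data generated in code; no files).

zt_grid <- seq(0, 21, by = 3)

# noise-free replicates drawn from a cosinor curve
make_cosinor_tr <- function(mesor = 10, amplitude = 6.2, acrophase = 10.5,
                            period = 24, n_rep = 5, zts = zt_grid) {
  timed_replicates(
    zts,
    lapply(zts, function(z)
      rep(mesor + amplitude * cos(2 * pi * (z - acrophase) / period), n_rep)),
    label = "fixture")
}

# the study's two ex-vivo damped-cosine parameter sets (female, male)
biolum_truth <- list(
  female = list(period = 24,    rel_amplitude = 1.27, acrophase = 19.22,
                damping_rate = 0.0054),
  male   = list(period = 26.58, rel_amplitude = 0.51, acrophase = 11.53,
                damping_rate = 0.0096))

# exact normalized damped-cosine series (mean-1 model form, no trend)
make_damped_series <- function(truth, duration_h = 144, dt_min = 10) {
  t <- seq(0, duration_h - dt_min / 60, by = dt_min / 60)
  y <- 1 + truth$rel_amplitude * exp(-truth$damping_rate * t) *
    cos(2 * pi * (t - truth$acrophase) / truth$period)
  list(t = t, y = y)
}

# small fast estimation setup: truth, config, and a generated dataset pair
make_estimation_fixture <- function(seed = 1, cv = 0, n_mice = 4,
                                    max_evals = 600) {
  truth <- reference_parameters()
  cfg <- estimation_config(truth, default_free_table(truth),
                           max_evals = max_evals)
  des <- experiment_design(n_mice_per_time = n_mice)
  dat <- gen_pk_experiment(des, truth,
                           noise_model(pk_inter_animal_cv = cv,
                                       pk_assay_cv = 0),
                           seed = seed)
  list(truth = truth, cfg = cfg, data = dat,
       true_theta = c(ka = truth$ka, k_ib = truth$k_ib,
                      k_pl_li = truth$k_pl_li, k_li_pl = truth$k_li_pl,
                      pgp_ileum_mesor = truth$pgp_ileum$mean_rate,
                      pgp_liver_mesor = truth$pgp_liver$mean_rate,
                      renal_mesor = truth$renal$mean_rate,
                      renal_phase = truth$renal$acrophases[1]))
}

# random valid parameter set for property tests
random_pbpk <- function() {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  crand <- function() circadian_rate(r(1e-4, 5),
                                     rel_amplitudes = stats::runif(1, 0, 0.9),
                                     periods = sample(c(24, 12, 8), 1),
                                     acrophases = stats::runif(1, 0, 24))
  pbpk_parameters(r(0.05, 5), r(0.05, 5), r(0.05, 5), r(0.05, 5),
                  pgp_ileum = crand(), pgp_liver = crand(),
                  renal = crand(), intestinal = crand())
}
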