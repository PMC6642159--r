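# chronopgp

Circadian physiologically-based pharmacokinetics of P-glycoprotein
substrates in the mouse.

P-glycoprotein (P-gp/ABCB1) is the efflux pump that rate-limits
intestinal absorption and drives biliary and renal excretion of many
drugs. Its expression oscillates over the day in a sex- and
feeding-dependent way, so *when* a P-gp substrate is dosed changes its
exposure. `chronopgp` implements, as a tested R package, the full
quantitative chain needed to study this with talinolol (a pure,
unmetabolized P-gp probe substrate) in mice — for
chronopharmacologists, PK modellers, and anyone building dosing-time
aware PBPK models:

* **Cosinor rhythmometry** for destructive-sampling circadian data:
  least-squares fit of
  `y(t) = M + Σ_k A_k cos(2π(t − φ_k)/T_k)` at periods 24, 12 and 8 h,
  with per-harmonic zero-amplitude partial F-tests
  (`fit_cosinor`, `predict_cosinor`).
* **Damped-cosine fitting** of multi-day ex-vivo bioluminescence,
  `y(t) = 1 + A e^{−λt} cos(2π(t − φ)/T)`, after linear detrending and
  mean-1 normalization (`detrend_normalize`, `fit_damped_cosine`).
* A **six-compartment circadian PBPK model** of oral dosing (gut lumen,
  ileum mucosa, plasma, liver, cumulative urine and feces) with
  cosine-modulated first-order rates for ileal P-gp efflux, hepatic
  (biliary) P-gp efflux, renal and intestinal elimination; compiled ODE
  right-hand side, strict mass balance (`simulate_pbpk`, `model_auc`).
* **Calibration** by weighted least squares over both dosing times
  jointly, minimized with CMA-ES under the biological constraints
  (clearance acrophases in ZT12–24, fasted amplitudes below fed), with
  virtual-dataset Monte-Carlo uncertainty for destructive sampling
  (`fit_group`, `monte_carlo_fit`).
* **Sobol global sensitivity** of liver/ileum AUC₀₋₈ₕ via Saltelli
  cross-sampling and the Jansen total-order estimator with bootstrap
  SDs (`run_sensitivity`).
* **Combinatorial non-compartmental summaries**: all one-mouse-per-time
  curve combinations, AUC₀₋₈ₕ and Cmax distributions
  (`combinatorial_curves`, `auc_cmax_stats`).
* A **synthetic-data generator** for all three experimental designs
  (`gen_expression`, `gen_pk_experiment`, `gen_bioluminescence`), so the
  whole pipeline is testable end to end without animal data.

## Worked example

Generate a circadian expression experiment (5 mice every 3 h) from a
known rhythm, fit the cosinor, then simulate and summarize talinolol PK
at the two study dosing times:

```r
library(chronopgp)

design <- experiment_design()
truth  <- cosinor_truth(mesor = 10, periods = 24, amplitudes = 6.2,
                        acrophases = 15)   # 62% relative amplitude, peak ZT15
expr <- gen_expression(design, truth, noise_model(expression_cv = 0.2),
                       seed = 1, label = "ileum P-gp protein, female, fed")
fit_cosinor(expr)
#> Cosinor fit (ileum P-gp protein, female, fed)
#>   mesor: 10.05   residual SS: 112   n: 40
#>  period amplitude acrophase      p_value
#>      24 5.8849403 14.897023 7.386745e-15
#>      12 0.5677233  9.160110 3.971256e-01
#>       8 0.3523698  2.669452 6.963448e-01
```

The 24 h component is recovered (amplitude 5.9 ≈ 6.2, acrophase
14.9 ≈ 15, p ≈ 1e−15) while the unused 12 h and 8 h harmonics stay
non-significant.

```r
p    <- reference_parameters()
sim3 <- simulate_pbpk(p, dose_event(zt_dose = 3))
sim3
#> PBPK simulation: dose 2500 ug at ZT3, 81 time points over 8.0 h
#>   Cmax plasma 49.1 ug/mL, ileum 5.15e+03 ug/g, liver 361 ug/g

sim15 <- simulate_pbpk(p, dose_event(zt_dose = 15))
model_auc(sim3, "ileum") / model_auc(sim15, "ileum")
#> [1] 1.19
```

Ileum exposure is highest (liver ~14×, plasma ~97× lower in AUC terms),
and dosing at ZT3 gives ~19% more ileum exposure than at ZT15 — the
dosing-time effect created by the circadian P-gp and clearance rhythms.

```r
pk <- gen_pk_experiment(experiment_design(n_mice_per_time = 4), p,
                        noise_model(pk_inter_animal_cv = 0.2), seed = 2)
auc_cmax_stats(pk[[1]], "ileum")
#> PK summary (F, fed, ZT3, ileum): 4096 curves (full enumeration)
#>   AUC0-8h 2.931e+04 +/- 2116, Cmax 5077 +/- 311.4
```

With 4 mice at each of 6 sacrifice times, all 4⁶ = 4096 one-mouse-per-
time-point curves are enumerated; the mean and SD summarize the
inter-animal spread of AUC and Cmax.

A command-line wrapper over the same functions is installed at
`inst/exec/chronopgp` (subcommands `synthesize`, `cosinor`,
`damped-cosine`, `simulate`, `auc`, `fit`, `mc-fit`, `sensitivity`).

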