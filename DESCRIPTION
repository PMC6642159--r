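Package: chronopgp
Title: Circadian Physiologically-Based Pharmacokinetics of P-gp Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying circadian (dosing-time dependent)
    pharmacokinetics of orally dosed P-glycoprotein substrates in mice.
    Implements multi-harmonic cosinor rhythmometry for destructive-sampling
    expression data, damped-cosine fitting for long ex-vivo bioluminescence
    recordings, a whole-body physiologically-based model of talinolol
    disposition with circadian-modulated P-gp efflux and clearances,
    weighted least-squares calibration via CMA-ES with Monte-Carlo
    resampling of sparse destructive-sampling designs, variance-based
    (Saltelli/Sobol) global sensitivity analysis, combinatorial
    non-compartmental AUC/Cmax summaries, and a synthetic-data generator
    emulating the three experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
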