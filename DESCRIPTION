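Package: vtbci
Title: Bayesian Causal Inference Modelling of Visuotactile Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computational psychophysics of body ownership and
    visuotactile simultaneity: a Bayesian causal inference (BCI) observer
    model with maximum-likelihood multistart fitting, pseudo-R2 goodness of
    fit and AIC/BIC model comparison with bootstrap confidence intervals;
    classical psychophysical measures (Gaussian temporal binding window,
    signal-detection d-prime and bias with half-trial padding, area under
    the d-prime curve); individual alpha frequency (IAF) estimation from
    Welch power spectra with a simplified aperiodic (1/f) correction; and
    synthetic observers, cohorts and EEG-like signals so every stage can be
    validated end-to-end by parameter recovery without raw experimental
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
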