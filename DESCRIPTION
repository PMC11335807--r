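Package: fearcomb
Title: Optimal Combination of Autonomic Threat-Conditioning Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for quantifying and optimally combining
    autonomic threat-conditioning readouts (skin conductance, pupil size,
    heart period and respiration amplitude responses). Provides dataset-wise
    scaling of CS+/CS- difference scores, participant screening, one-sample
    Cohen's d for single measures and for linear combinations, closed-form
    d-maximizing combination weights (Fisher discriminant against the
    origin), minimum-residual exploratory factor analysis with Monte-Carlo
    parallel analysis and empirical p-values for factor retention, repeated
    k-fold out-of-sample validation of the combination rule with
    bias-corrected confidence intervals, exact noncentral-t power and
    sample-size planning, and a latent-factor synthetic-data generator that
    emulates multi-dataset designs with heterogeneous measure availability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
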