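Package: rsvpnet
Title: Sequential Object-Recognition Networks with Intrinsic Suppression for RSVP Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sequential object recognition in rapid serial visual
    presentation (RSVP) streams using recurrent rate networks whose rectified
    units carry activation-based intrinsic suppression (exponential or
    power-law adaptation). Provides prototype-based readout of
    representational strength over time, signal-detection sensitivity (d'
    from ROC-AUC over peak prototype correlations, and the log-linear
    correction for binary human reports), and a trial-by-trial model-human
    comparison pipeline: Spearman predictivity per model step and
    presentation duration, subject-level bootstrap confidence intervals,
    leave-one-out noise ceilings, temporal correspondence and explanatory
    power. Ships a synthetic-data generator for toy image categories, RSVP
    trial sets and simulated observer panels so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
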