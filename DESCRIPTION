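Package: emcscreen
Title: Eye-Movement Correlogram Screening for Visual Field Defects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening for visual field defects from eye movements recorded
    during a continuous tracking task. Provides a stimulus generator for
    Gaussian-random-walk and displaced (jumping) target trajectories, an
    observer simulator with configurable pursuit latency, positional noise,
    blink artifacts and reacquisition behaviour, a blink-repair
    preprocessing pipeline, extraction of the 40 spatiotemporal properties
    of eye movements via velocity cross-correlograms, positional error
    distributions, cosine similarity and Kalman observation-noise
    estimation, robust normative scoring with modified Z-scores, and
    Gini decision-tree classification with cross-validated tuning,
    leave-one-out evaluation and full diagnostic metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rpart
Config/testthat/edition: 3
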