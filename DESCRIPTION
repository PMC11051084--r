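Package: lapsepipe
Title: Interruption Detection and Period Inference for Online-Learning Event Logs
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects learner interruptions in timed interaction logs from
    online-learning platforms. Implements three duration-outlier classifiers
    (per-item mean + k SD thresholds; learner speed-factor adjusted thresholds;
    MAD-based modified Z-scores on log durations), reconstruction of digital
    sessions from inactivity gaps with long-interruption counting, and
    calendar-period inference (rates by month and named period, tests of equal
    proportions, Cohen's h against a smallest effect size of interest). A
    synthetic event-log generator with ground-truth interruption labels makes
    every stage testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
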