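Package: neutrochisq
Title: Neutrosophic Chi-Square Tests for Interval-Valued Count Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Chi-square dispersion tests for K counts recorded as
    indeterminate intervals rather than exact values.  Provides the
    equal-observation-time and unequal-observation-time interval test
    statistics, the a + b*I neutrosophic-form decomposition with its
    indeterminacy measure, a two-sided critical-region decision rule with
    an explicit indeterminate outcome, Monte-Carlo estimation of rejection
    rates over simulated interval counts, CSV input/output with a bundled
    50-patient pulse-count example, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
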