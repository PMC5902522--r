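Package: plausr
Title: Posterior Plausibility of Statistical Model Assumptions After Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how plausible a statistical model assumption is after it
    has been checked with a null-hypothesis significance test. A nonsignificant
    assumption check (for example Levene's test of equal variances before a
    Student t test) only licenses belief in the assumption to the degree that
    the assumption was plausible beforehand and the check was powerful against
    the violations one considers plausible. The package provides closed-form
    prior-to-posterior updating of assumption plausibility given a test outcome
    or a Bayes factor, catch-all Type II error rates under a prior over
    violations of the equal-variances assumption, wrong-acceptance-rate tables,
    the frequentist two-group tests used in the gated Levene-then-t workflow,
    and seeded Monte Carlo machinery that validates the analytic error rates
    and measures the operating characteristics of gated testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
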