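Package: rankprob
Title: Ranking Probabilities and the Ranking False Discovery Rate for
    Large-Scale Multiple Testing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and analysis tools for studies with many statistical
    tests, built around ranking probabilities: the chance that at least t
    true signals rank among the u smallest P-values of an experiment.
    Computes P-value distributions under noncentral chi-square
    alternatives with point-mass, tabulated, or Gamma effect-size
    (noncentrality) models; ranking probabilities and the expected number
    of true discoveries among top hits; the ranking false discovery rate
    (rFDR) and posterior null probabilities; power relations; inverse
    design questions (number of top hits or sample size needed for a
    target yield); and a Monte Carlo simulator that validates every
    closed-form approximation. Includes a command-line interface for
    scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
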