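Package: soundchoice
Title: Analysis of Auditory Two-Alternative Choice Behavior and Striatal Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rodent auditory two-alternative choice experiments.
    Provides a synthetic-session generator with known ground truth
    (logistic choice behavior with lapses, optogenetic choice bias,
    switching blocks with a moving categorization boundary,
    piecewise-constant-rate Poisson units, marker-based head pose);
    psychometric summaries and constrained maximum-likelihood logistic
    fits; event-aligned spike counting and nonparametric modulation
    indices (sound response, high/low frequency selectivity, movement
    and choice modulation); a binned z-score responsiveness criterion;
    contingency-switching analysis with a multi-switch consistency
    rule; head-angle estimation from marker centroids; and
    population-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
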