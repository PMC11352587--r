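Package: fastvision
Title: Constrained Maximum-Entropy Sketches and Flicker-Adaptation Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a contrast-discrimination psychophysics pipeline built
    around image "sketches": compressed renderings of binary images that retain
    only the pixels whose local 3x3 patch belongs to a feature set chosen to
    maximize Shannon entropy under a feature-count cap (N) and a total
    probability bandwidth cap (W). The package extracts patch statistics from
    images, selects optimal feature sets (greedy and exact solvers), renders
    sketches and the companion stimuli of a three-task two-alternative
    forced-choice (2AFC) experiment (drifting and tilted noisy Gabors, a 10 Hz
    flicker adapter, random-pixel masks), simulates a synthetic observer cohort
    with cumulative-Gaussian psychometric behaviour, fits psychometric
    functions by maximum likelihood to extract 75-percent-correct contrast
    thresholds, and runs the nonparametric analysis chain: paired Wilcoxon
    signed-rank tests with rank-biserial effect sizes and bootstrap confidence
    intervals, Friedman tests with Kendall's W, and Conover post hoc
    comparisons with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
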