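Package: ordtime
Title: Bayesian Modeling of Order Effects on Memory for Event Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how memorized serial order biases memory for
    absolute event times within an episode. Simulates slot-based time-report
    experiments (anchored first/last items, intermediate items in random
    distinct slots, continuous slider reports), estimates the single-item
    time-report likelihood empirically, decodes absolute presentation times
    by Bayesian inference over noisy internal times combined with a
    discretely corrupted internal order representation, and provides the
    ordering-accuracy and report-curve analyses used to compare measured
    behavior against naive independent-encoding predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
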