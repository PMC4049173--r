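Package: zebratrain
Title: Simulation and Analysis of Cerebellar Purkinje Cell Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing extracellular Purkinje cell recordings in
    which simple spikes and complex spikes have been labelled, together with
    a point-process generator of synthetic recordings for testing every
    analysis stage at desk scale. Per-cell statistics (firing rate, interspike
    interval CV, mean CV2, climbing fiber pause, 30-s stability profiles,
    inclusion filters), complex spike waveform metrics (half-maximum width,
    rectified spike area), peri-complex-spike histograms with a four-way
    response-type classifier, and the group-level statistics used to compare
    zebrin-positive and zebrin-negative populations (pooled two-sample t,
    paired t, Pearson chi-squared, Spearman/Pearson correlation, one-way
    ANOVA with post hoc tests, drug wash-in effect, f-I slope). A pipeline
    runner orchestrates simulate -> metrics -> peri-CS -> stats into a single
    reproducible, seeded run.
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
    withr,
    optparse
Config/testthat/edition: 3
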