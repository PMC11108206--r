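Package: rhythmnet
Title: Circadian Rhythm Detection and Network Phase Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rhythmic genes from replicated bulk RNA-seq circadian
    time courses by harmonic (cosinor) regression with a dual-experiment
    consensus criterion and an analytic false-discovery calculus;
    characterizes phase distributions with circular statistics (circular
    means and correlation, the Watson-Wheeler uniform-scores test, a
    circular median sign test, and two-component von Mises mixture
    fitting); and tests for phase organization of cycling genes on a gene
    interaction network via a geodesic-distance phase-difference profile
    compared against a permutation null. Includes a synthetic-data module
    that emulates a two-experiment, two-temperature study design with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
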