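Package: scenegaze
Title: Saliency-Referenced Analysis of Gaze Behavior in Natural Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how low-level visual saliency and social
    scene content (heads, bodies) compete for overt attention. Implements
    graph-based visual saliency maps via Markov-chain equilibria,
    velocity/acceleration-based fixation and saccade detection with
    baseline drift correction and recursive outlier removal, percentile
    partitions of scenes into regions of interest, duration-weighted
    Gaussian-smoothed fixation density maps, area-normalized attention
    metrics, and repeated-measures inference (Huynh-Feldt corrected ANOVA,
    generalized eta squared, noncentral-F power). A synthetic-data module
    generates scenes with planted social regions and simulates gaze
    recordings with known ground truth so the full pipeline is testable
    without proprietary stimuli or recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    png,
    jpeg,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
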