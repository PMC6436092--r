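Package: cdk2flux
Title: Simulation and Quantification of Fluctuating CDK2 Activity in S Phase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying stochastic replication-stress-driven
    fluctuations in CDK2 activity during S phase from live-cell reporter
    imaging. Provides a Monte Carlo trace simulator in which CDK2 activity
    ramps linearly through S phase and is transiently suppressed by
    Gaussian-shaped stress dips, a synthetic multi-channel microscopy
    renderer with per-cell ground truth, an image quantification chain
    (nuclear segmentation, global background estimation, perinuclear-ring
    cytoplasmic measurement, top-hat puncta counting, centroid tracking),
    per-cell trace statistics (polynomial-residual and second-derivative
    fluctuation metrics, landmark calling, S-phase slope, drug-washout
    recovery kinetics, autocorrelation), and population-level analyses
    (EdU/BrdU pulse-chase rate analysis, S-phase duration estimation,
    group and time-series statistics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
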