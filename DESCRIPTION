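Package: sfsmix
Title: Tajima's D and Site-Frequency-Spectrum Skew for Mixtures of
    Neutral and Strongly Selected Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytic and simulation tools for the behaviour of Tajima's D
    and the skew statistic delta-theta-w = 1 - pi/theta_w in short sequence
    windows that contain a mixture of neutral sites and sites under strong
    purifying selection at mutation-selection balance. Provides the
    sample-size constants and window statistics of Tajima's D, the expected
    D under the neutral equilibrium infinite-sites coalescent as a function
    of the window-scaled mutation rate, an inversion from a mean D and mean
    pairwise diversity to the implied mean number of segregating sites, the
    neutral/selected mixture model with parameter sweeps over selection
    strength and neutral-site proportion, a coalescent window simulator
    (with exponential growth calibrated to a target mean D) serving as an
    independent oracle, and plumbing to write and scan ms-format and VCF
    windows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
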