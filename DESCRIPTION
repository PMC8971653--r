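Package: endotime
Title: Continuous Temporal Staging of Luteal-Phase Endometrial Biopsies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the temporal state of luteal-phase endometrial biopsies
    on a continuous day scale (days after the urinary LH surge) from the
    expression of a small panel of marker genes measured by RTq-PCR or
    RNA-seq. Implements an iterative refinement scheme that alternates
    between building windowed Gaussian temporal profiles for each gene and
    re-estimating per-sample timings as the maxima of aggregated likelihood
    curves, with a shrinking window schedule and Euclidean-distance
    convergence. Includes qPCR delta-CT preprocessing and additive batch
    correction, continuization of integer reported timings, an asynchrony
    score with segmented-regression outlier flagging, moment-matching
    calibration of RNA-seq TPM values onto the qPCR scale, leave-one-out
    validation with conservative tie-breaking and one-sided Wilcoxon
    rank-sum testing, greedy marker-panel reduction, and a synthetic-cohort
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
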