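Package: squealfiber
Title: Acoustic and Fiber-Microscopy Assessment of Vocal Fold Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of vocal fold recovery after laryngeal
    surgery in a voicing animal model, from two complementary data streams.
    The acoustic arm segments spontaneous high-pitched vocalizations
    (squeals) from long-form recordings by a moving-average volume rule and
    computes six voice parameters (Q50, two spectral-flux variants, Mel
    spectral spread, P60 and the 8th order-16 LPC coefficient), screens
    candidate features by the overlap of pre- and post-surgery Gaussian
    fits, quantifies feature redundancy with bias-corrected distance
    correlation, and tests longitudinal change with date-balanced one-sided
    Wilcoxon rank-sum tests under Bonferroni control. The imaging arm
    quantifies collagen and elastin fiber organization in two-channel
    nonlinear-microscopy mosaics: filtering, Otsu masking, particle
    removal, per-pixel local gradient orientation, directionality
    histograms, two-pass normal-curve fits (alignment, dispersion,
    goodness of fit) and the cross-channel alignment difference. Seeded
    synthetic squeal cohorts and fiber phantoms with known ground truth
    make every stage testable without raw recordings or slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
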