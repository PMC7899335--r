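Package: glrquant
Title: Quantification of Synaptic Receptor Imaging and Behavioral Assays in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the image and behavior quantification
    pipeline used to study surface levels of the AMPA-type glutamate receptor
    GLR-1 in C. elegans neurons: puncta calling on fluorescence line scans
    (threshold and minimum-width rules, FWHM widths, per-10-micron densities,
    bead normalization), dual SEP/mCherry pH-quenching quantification of the
    receptor surface fraction (threshold calibration, thresholded integrated
    densities, ratio normalization, model-based surface-fraction inversion),
    dual-channel FRAP recovery analysis (nested ROI geometry, pre-bleach
    normalization, single-exponential recovery fits, repeated-measures
    comparison), and behavioral assay scoring (nose touch, optogenetic ASH
    activation, thrashing, aldicarb paralysis, spontaneous reversals) with the
    group-comparison statistics implemented from first principles (t, one-way
    ANOVA, Tukey HSD, Dunnett, two-way repeated-measures ANOVA). A synthetic
    data generator with full ground-truth records emulates every modality so
    each stage is testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
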