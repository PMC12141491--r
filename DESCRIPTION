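Package: fluoroplast
Title: Chlorophyll Fluorescence and Chloroplast Shape Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies photosynthetic light-acclimation state and chloroplast
    morphology from three standard assays: 77 K chlorophyll fluorescence
    emission spectra (smoothing, baseline subtraction, PSII-peak normalization
    and the normalized PSI fluorescence statistic used to read out state
    transitions, with dilution-series self-absorption QC), pulse-amplitude
    modulation (PAM) fluorometry traces (Fv/Fm, PSII yield, NPQ, F0', qL,
    relative electron transport rate and rapid light curves), and fluorescence
    micrographs of chloroplasts (segmentation, area, sub-pixel perimeter and
    circularity with per-replicate median aggregation). Group comparisons
    follow a normality/variance-gated decision tree (Student's t or one-way
    ANOVA with Tukey post hoc, else Kruskal-Wallis with Dunn post hoc). A
    synthetic-data generator produces spectra, PAM traces and chloroplast
    scenes with analytic ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    car,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
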