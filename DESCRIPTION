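Package: fifplan
Title: Automated Field-in-Field Planning for Whole-Brain Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-planned field-in-field (FIF) homogenization for
    whole-brain radiotherapy with two opposed lateral beams. Provides a
    reproducible synthetic head phantom (density grid plus brain, body,
    bone, eye and lens masks), a raycast megavoltage dose model, beam's-eye-view
    projection with multi-leaf-collimator aperture conformance, the iterative
    FIF loop (hotspot detection by 3D connected components, iso-dose decrement
    thresholding, opposed subfield pairs, bounded quasi-Newton beam-weight
    optimization, coverage normalization, three-way stopping rule), and
    dose-volume-histogram plan evaluation with tidy reports and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    tibble,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
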