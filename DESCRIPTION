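Package: boldqc
Title: Coefficient-of-Variation Quality Control and Gray-Matter Group ICA
    for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise coefficient-of-variation (CV) mapping for resting-state
    BOLD quality control against a normative reference, with automated stripe
    and widespread-signal-defect scoring; temporal signal-to-noise ratio
    comparison of included and excluded runs; a minimal FSL-style
    preprocessing chain (initial volume dropping, Gaussian running-line
    high-pass filtering, isotropic Gaussian smoothing, gray-matter masking);
    temporal-concatenation group spatial ICA with Gaussian/gamma mixture map
    thresholding and template-based network identification; dual regression
    with max-statistic permutation inference; and a seeded synthetic BOLD
    phantom cohort generator with embedded networks, tissue compartments,
    atrophy and artifact classes for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
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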