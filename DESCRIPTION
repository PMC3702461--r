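Package: pction
Title: Classification-Based Pseudo-CT Synthesis from Multi-Contrast MRI for Ion-Beam Range Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives pseudo CT numbers from co-registered multi-contrast MR
    volumes by voxelwise classification into fixed-width Hounsfield-unit
    classes using a subspace Gaussian discriminant model (per-class
    low-dimensional signal subspace plus isotropic noise), and converts the
    result to water-equivalent path length through an empirical Hounsfield
    lookup table to quantify water-equivalent-thickness and beam-range
    errors, including a target-shift adaptation experiment.  Ships a seeded
    digital-phantom generator (piecewise-homogeneous tissue regions, MR
    sequence signal models, partial-volume mixing, bias field, Rician and
    Gaussian noise) so the whole pipeline is testable end to end without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
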