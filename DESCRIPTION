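Package: iclm
Title: Independent Component-Based Lesion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps patient lesion masks through a normative resting-state
    functional connectome, decomposes the pooled lesion-seeded connectivity
    matrix into spatially independent networks with multi-restart Infomax
    ICA and cross-ISI run selection, identifies the symptom-related network
    against reference maps, and scores per-patient network damage for
    brain-behavior correlation. Includes voxel-based lesion-symptom mapping
    (VLSM) and overlay lesion network mapping (LNM) baselines, a fully
    synthetic cohort generator, and reproducibility/stability/specificity
    validation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
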