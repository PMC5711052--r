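Package: rtcohort
Title: Dose-Volume, Radiobiological and Cohort Comparison of Radiotherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation pipeline for external-beam radiotherapy treatment
    plans: computes dose-volume histograms from voxel dose grids and binary
    structure masks, derives plan-quality indices (homogeneity index,
    conformity index, conformation number), Niemierko-model radiobiological
    indices (generalized equivalent uniform dose, tumor control probability,
    normal-tissue complication probability), checks plans against clinical
    acceptance constraints, and compares plan cohorts across treatment
    modalities (conformal radiotherapy, intensity-modulated radiotherapy,
    volumetric-modulated arc therapy) with one-way ANOVA and Tukey HSD post
    hoc tests. Includes a deterministic synthetic thorax phantom and dose
    generator so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
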