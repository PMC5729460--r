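Package: plaqueCT
Title: CT-Based Carotid Plaque Component Analysis and Calcification Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of carotid atherosclerotic plaque
    on computed tomography. Classifies plaque voxels into five Hounsfield-unit
    tissue bands (lipid, fibrolipid, fibrotic, fibrocalcified, calcification)
    and applies a vulnerable/stable decision rule with lipid and ulceration
    overrides; computes an Agatston-style carotid calcification score (CALS)
    by per-slice connected-component lesion extraction, peak-HU weighting,
    minimum-area filtering and slice-thickness adjustment, identically for
    contrast CTA and non-contrast CT; encodes the histological ground-truth
    model (binary intraplaque haemorrhage, ordinal 0-3 micro- and
    macrocalcification grades); and provides the diagnostic-validation
    statistics (sensitivity, specificity, PPV and NPV with Wilson or
    Clopper-Pearson intervals, Mann-Whitney with mean ranks, Spearman
    correlation, Bland-Altman agreement with drift, Cohen's kappa with Fleiss
    interpretation bands). A synthetic-phantom module generates CT volumes
    with planted components, calcified lesions, a contrast-filled lumen and
    blooming artifacts, plus cohort tables with configurable prevalence and
    test operating characteristics, so every stage has an analytic oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
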