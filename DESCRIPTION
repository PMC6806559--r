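Package: ictosr
Title: MRI Radiomic Treatment-Benefit Modelling for Induction Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates an MRI radiomic treatment-benefit biomarker
    (ICTOS, Induction Chemotherapy Outcome Score) for locoregionally advanced
    nasopharyngeal carcinoma: 2D radiomic feature extraction (first-order
    intensity, shape, gray-level co-occurrence and run-length matrices),
    intraclass-correlation reproducibility screening, inverse probability of
    treatment weighting, interaction screening and modified-covariate Cox
    modelling of treatment benefit, weighted Kaplan-Meier evaluation with
    Greenwood confidence intervals, log-rank power calculations, and risk
    stratification. Includes a synthetic phantom and cohort generator with
    known ground truth so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    survival,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
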