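Package: ropscreen
Title: Interpretable Severity Screening for Retinopathy of Prematurity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretable screening pipeline for retinopathy of
    prematurity (ROP). Per-field fundus lesion detections are re-projected
    onto a per-eye panoramic montage via similarity-transform registration,
    disease stage is derived from the most severe lesion type, zone from
    lesion position under geometric ICROP templates centred on the optic
    disc, and plus disease from vessel tortuosity and dilation features on
    the disc-centred field. Stage, zone and plus are integrated into an
    ETROP-style binary severity call by an explicit rule engine, with a
    full evaluation suite (Cohen's kappa, accuracy, sensitivity,
    specificity, F1, ROC/AUC with bootstrap confidence intervals, and
    specificity at full recall). A seeded synthetic-eye generator renders
    multi-field rasters with known transforms, landmarks, vessels and
    lesions so that every stage of the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    glmnet,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
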