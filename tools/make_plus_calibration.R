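# Produces inst/extdata/plus_calibration.json: the fixed coefficients of the
# plus-disease logistic score, calibrated once on 200 seeded synthetic
# disc-centred fields (balanced classes, seed 2024).  Run from the repo root.
library(ropscreen)
cal <- calibrate_plus_model(n = 200, seed = 2024)
stopifnot(all(cal$coef >= 0), cal$train_accuracy >= 0.99)
jsonlite::write_json(cal, "inst/extdata/plus_calibration.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("train accuracy:", cal$train_accuracy, "coef:", cal$coef, "\n")
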