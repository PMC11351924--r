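# Independent oracles used across the suite.  Each is a deliberately
# naive computation (brute force, enumeration, quadrature) kept separate
# from the implementation it checks.

# Mann-Whitney rank statistic by explicit pairwise comparison.
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# Best specificity subject to sensitivity == 1, by exhaustive threshold
# search over the observed scores.
brute_spec_full_recall <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- 0
  for (thr in sort(unique(scores))) {
    pred <- scores >= thr
    if (all(pred[labels])) best <- max(best, mean(!pred[!labels]))
  }
  best
}

# Severity lookup transcribed by hand, row by row, from the clinical
# criteria: everything in zone I; stage 2 + plus in zone II; stage 3 in
# zone II; stage 4 anywhere; all else mild.
hand_severity_table <- function() {
  rows <- list(
    # stage, zone, plus, severity
    list(0L, "none", FALSE, "not_severe"), list(0L, "none", TRUE, "not_severe"),
    list(1L, "I", FALSE, "severe"), list(1L, "I", TRUE, "severe"),
    list(2L, "I", FALSE, "severe"), list(2L, "I", TRUE, "severe"),
    list(3L, "I", FALSE, "severe"), list(3L, "I", TRUE, "severe"),
    list(4L, "I", FALSE, "severe"), list(4L, "I", TRUE, "severe"),
    list(1L, "II", FALSE, "not_severe"), list(1L, "II", TRUE, "not_severe"),
    list(2L, "II", FALSE, "not_severe"), list(2L, "II", TRUE, "severe"),
    list(3L, "II", FALSE, "severe"), list(3L, "II", TRUE, "severe"),
    list(4L, "II", FALSE, "severe"), list(4L, "II", TRUE, "severe"),
    list(1L, "III", FALSE, "not_severe"), list(1L, "III", TRUE, "not_severe"),
    list(2L, "III", FALSE, "not_severe"), list(2L, "III", TRUE, "not_severe"),
    list(3L, "III", FALSE, "not_severe"), list(3L, "III", TRUE, "not_severe"),
    list(4L, "III", FALSE, "severe"), list(4L, "III", TRUE, "severe"))
  do.call(rbind, lapply(rows, function(r)
    data.frame(stage = r[[1]], zone = r[[2]], plus = r[[3]],
               severity = r[[4]], stringsAsFactors = FALSE)))
}

# Closed-form expected stage accuracy for a set of eyes under a pure
# type-confusion noise model (no misses, no false positives): the
# predicted stage is the max of independent per-lesion reported types,
# so P(correct) = P(all reported <= s) - P(all reported <= s - 1) for a
# stage-s eye, and 1 for a lesion-free eye.
expected_stage_accuracy <- function(eye_lesion_types, confusion) {
  cdf <- t(apply(confusion, 1, cumsum))
  p_correct <- vapply(eye_lesion_types, function(types) {
    if (length(types) == 0) return(1)
    s <- max(types)
    ple <- function(v) if (v == 0) 0 else prod(cdf[types, v])
    ple(s) - ple(s - 1)
  }, numeric(1))
  list(mean = mean(p_correct),
       se = sqrt(sum(p_correct * (1 - p_correct))) / length(p_correct))
}

# A structured random raster for registration tests: smooth blobs plus a
# weak global gradient, seeded.
blob_raster <- function(size = 192, n_blobs = 30, seed = 1) {
  set.seed(seed)
  img <- matrix(0, size, size)
  for (k in seq_len(n_blobs))
    img <- ropscreen:::draw_disk(img,
                                 c(runif(1, 20, size - 20), runif(1, 20, size - 20)),
                                 runif(1, 3, 9), runif(1, 0.3, 1))
  img + 0.05 * sin(outer(seq_len(size), seq_len(size), "+") / 11)
}

# Small deterministic frame used across zoning tests.
test_frame <- function(d_df = 150, ora = 450)
  panorama_frame(c(550, 550), c(550 - d_df, 550), ora, "OD")
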