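test_that("eye generation is deterministic and honours the configuration", {
  cfg <- eye_config()
  e1 <- generate_eye(cfg, seed = 7)
  e2 <- generate_eye(cfg, seed = 7)
  expect_identical(e1$lesions, e2$lesions)
  expect_identical(e1$vessel_angles, e2$vessel_angles)
  expect_identical(e1$plus_present, e2$plus_present)

  # zero lesion rate: lesion-free eye
  cfg0 <- eye_config(lesion_probs = c(0, 0, 0, 0))
  e0 <- generate_eye(cfg0, seed = 7)
  expect_equal(nrow(e0$lesions), 0)
  expect_equal(eye_stage(e0$lesions), 0L)

  # a lesion forced next to the disc lies in zone I (the posterior pole,
  # fovea included, is inside zone I by construction)
  cfgI <- eye_config(lesion_probs = c(0, 0, 0, 1),
                     lesion_radius_range = c(70, 120))
  eI <- generate_eye(cfgI, seed = 3)
  expect_equal(nrow(eI$lesions), 1)
  expect_equal(eI$lesions$true_zone, "I")
  expect_equal(eI$lesions$type, 4)

  # infeasible geometry rejected
  expect_error(eye_config(ora_radius = 250), "infeasible")
})

test_that("generated lesion frequencies match the configured rates", {
  cfg <- eye_config()
  n <- 200
  counts <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    eye <- generate_eye(cfg, seed = 40000 + i)
    for (t in 1:4) counts[i, t] <- sum(eye$lesions$type == t)
  }
  # per-type presence is Bernoulli(p): binomial 3-standard-error band
  for (t in 1:4) {
    p <- cfg$lesion_probs[[t]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(counts[, t] > 0) - p), 3 * se + 1e-9)
  }
})

test_that("the default camera plan has one disc-centred field and real overlap", {
  eye <- generate_eye(eye_config(), seed = 1)
  plan <- eye$plan
  expect_equal(sum(plan$orientation_label == "disc_centered" |
                     plan$orientation_label == "disc-centered"), 1)
  tr <- attr(plan, "transforms")
  # disc-centred field maps its centre onto the disc
  f1 <- plan$field_id[plan$orientation_label %in% c("disc_centered", "disc-centered")]
  expect_equal(st_apply(tr[[f1]], c(plan$width[1] / 2, plan$height[1] / 2)),
               eye$disc_center)
  # every peripheral field overlaps the anchor by >= 25% of its area
  for (i in seq_len(nrow(plan))) {
    if (plan$field_id[i] == f1) next
    b <- st_map_box(tr[[plan$field_id[i]]],
                    c(0, 0, plan$width[i], plan$height[i]))
    a <- st_map_box(tr[[f1]], c(0, 0, plan$width[1], plan$height[1]))
    ov <- max(0, min(b[3], a[3]) - max(b[1], a[1])) *
      max(0, min(b[4], a[4]) - max(b[2], a[2]))
    expect_gte(ov / (plan$width[i] * plan$height[i]), 0.25)
  }
})

test_that("field ground-truth boxes round-trip to panorama boxes within 1 px", {
  eye <- generate_eye(eye_config(lesion_probs = c(1, 1, 1, 1)), seed = 9)
  gt <- field_ground_truth(eye)
  tr <- attr(eye$plan, "transforms")
  for (k in seq_len(nrow(gt))) {
    if (gt$clipped[k]) next
    back <- st_map_box(tr[[gt$field_id[k]]],
                       as.numeric(gt[k, c("x0", "y0", "x1", "y1")]))
    truth <- as.numeric(eye$lesions[
      eye$lesions$lesion_id == gt$lesion_id[k], c("x0", "y0", "x1", "y1")])
    expect_lt(max(abs(back - truth)), 1)
  }
  # every lesion is visible (unclipped) in at least one field
  unclipped <- gt[!gt$clipped, ]
  expect_setequal(unique(unclipped$lesion_id), eye$lesions$lesion_id)
})

test_that("a lesion straddling two fields appears clipped in one, whole in another", {
  # place a single large lesion near the nasal field border
  cfg <- eye_config(lesion_probs = c(0, 0, 1, 0), lesion_radius_range = c(280, 340),
                    lesion_extent_range = c(50, 64))
  found <- FALSE
  for (s in 1:60) {
    eye <- generate_eye(cfg, seed = 60000 + s)
    if (nrow(eye$lesions) != 1) next
    gt <- field_ground_truth(eye)
    if (length(unique(gt$field_id)) >= 2 && any(gt$clipped) && any(!gt$clipped)) {
      found <- TRUE
      tr <- attr(eye$plan, "transforms")
      # union of re-projected boxes covers the panorama box within 1 px
      backs <- t(sapply(seq_len(nrow(gt)), function(k)
        st_map_box(tr[[gt$field_id[k]]],
                   as.numeric(gt[k, c("x0", "y0", "x1", "y1")]))))
      union_box <- c(min(backs[, 1]), min(backs[, 2]),
                     max(backs[, 3]), max(backs[, 4]))
      truth <- as.numeric(eye$lesions[1, c("x0", "y0", "x1", "y1")])
      expect_lt(max(abs(union_box - truth)), 1)
      break
    }
  }
  expect_true(found)
})

test_that("rendered fields show the scene and vessels at the configured width", {
  eye <- generate_eye(eye_config(plus_prevalence = 0), seed = 21)
  rf <- render_fields(eye, fields = "F1")
  r <- rf$rasters[["F1"]]
  expect_equal(dim(r), c(480, 640))
  expect_true(all(r >= 0 & r <= 1))
  # bright disc at the field centre
  expect_gt(r[241, 321], 0.9)
  # vessel pixels exist in the mid-intensity band
  expect_gt(sum(ropscreen:::vessel_mask(r)), 1000)
  expect_equal(nrow(rf$report), 0)
})
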