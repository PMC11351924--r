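test_that("pairwise estimation recovers identity, shifts and rotations", {
  img <- blob_raster(192, seed = 1)

  e0 <- estimate_pairwise(img, img)
  expect_gt(e0$score, 0.99)
  expect_lt(abs(e0$transform$scale - 1), 0.01)
  expect_lt(abs(e0$transform$rotation), 0.01)
  expect_lt(sqrt(e0$transform$tx^2 + e0$transform$ty^2), 0.5)

  # known shift (+20, -10): fixed = moving shifted by (+20, -10)
  shift <- sim_transform(1, 0, 20, -10)
  fixed <- ropscreen:::warp_raster(img, shift, 192, 192, fill = mean(img))
  es <- estimate_pairwise(fixed, img)
  expect_lt(abs(es$transform$tx - 20), 0.5)
  expect_lt(abs(es$transform$ty + 10), 0.5)
  expect_lt(abs(es$transform$rotation), 0.01)

  # known rotation of 10 degrees about the centre
  rot <- ropscreen:::st_about(1, 10 * pi / 180, c(96, 96))
  fixed_r <- ropscreen:::warp_raster(img, rot, 192, 192, fill = mean(img))
  er <- estimate_pairwise(fixed_r, img)
  expect_lt(abs(er$transform$rotation - 10 * pi / 180), 0.5 * pi / 180)

  expect_error(estimate_pairwise(matrix(0.5, 64, 64), matrix(0.5, 64, 64)),
               "constant")
})

test_that("transform recovery stays accurate over randomized similarity pairs", {
  img <- blob_raster(192, n_blobs = 40, seed = 2)
  set.seed(17)
  terr <- rerr <- numeric(30)
  for (i in 1:30) {
    s <- runif(1, 0.9, 1.1)
    th <- runif(1, -15, 15) * pi / 180
    d <- runif(2, -0.3, 0.3) * 192
    tr <- ropscreen:::st_about(s, th, c(96, 96), d)
    fixed <- ropscreen:::warp_raster(img, tr, 192, 192, fill = mean(img))
    est <- estimate_pairwise(fixed, img)$transform
    rerr[i] <- abs(est$rotation - th) * 180 / pi
    terr[i] <- sqrt((est$tx - tr$tx)^2 + (est$ty - tr$ty)^2)
  }
  expect_lt(median(terr), 1)
  expect_lt(median(rerr), 0.5)
})

test_that("montage composition recovers generator transforms and chains exactly", {
  # single field: identity montage
  img <- blob_raster(128, seed = 3)
  m1 <- compose_montage(list(A = img), anchor = "A")
  expect_equal(ropscreen:::st_params(m1$transforms[["A"]]),
               ropscreen:::st_params(st_identity()))
  expect_equal(m1$panorama, img)

  # 5-field synthetic plan: recovered globals within 1 px of truth
  eye <- generate_eye(eye_config(), seed = 12)
  rf <- render_fields(eye)
  tr_true <- attr(eye$plan, "transforms")
  mont <- compose_montage(rf$rasters, anchor = "F1", rotation_scale = FALSE)
  t_anchor <- tr_true[["F1"]]
  for (f in eye$plan$field_id) {
    # montage frame is anchored at F1, generator frame at the panorama:
    # truth in montage coordinates is inv(T_F1) o T_f
    truth <- st_compose(st_inverse(t_anchor), tr_true[[f]])
    got <- mont$transforms[[f]]
    ctr <- c(320, 240)
    expect_lt(sqrt(sum((st_apply(got, ctr) - st_apply(truth, ctr))^2)), 1)
  }

  # chaining A-B-C with exact pairwise transforms composes exactly
  tab <- sim_transform(1.1, 0.1, 30, -12)   # B -> A
  tbc <- sim_transform(0.95, -0.2, -8, 25)  # C -> B
  pairs <- list(list(fixed = "A", moving = "B", transform = tab, score = 1),
                list(fixed = "B", moving = "C", transform = tbc, score = 1))
  small <- blob_raster(64, seed = 4)
  m <- compose_montage(list(A = small, B = small, C = small), anchor = "A",
                       pairwise = pairs)
  expect_equal(ropscreen:::st_params(m$transforms[["C"]]),
               ropscreen:::st_params(st_compose(tab, tbc)), tolerance = 1e-6)

  # disconnected graph errors and names the unreachable field
  pairs2 <- list(list(fixed = "A", moving = "B", transform = tab, score = 1),
                 list(fixed = "B", moving = "C", transform = tbc, score = 0.1))
  expect_error(compose_montage(list(A = small, B = small, C = small),
                               anchor = "A", pairwise = pairs2), "C")
})

test_that("lesion mapping is exact for simple transforms and merges duplicates", {
  dets <- data.frame(field_id = "A", type = 2L, x0 = 10, y0 = 20, x1 = 40,
                     y1 = 50, confidence = 0.9, stringsAsFactors = FALSE)
  # identity
  out <- map_lesions(dets, list(A = st_identity()))
  expect_equal(as.numeric(out[1, c("x0", "y0", "x1", "y1")]), c(10, 20, 40, 50))
  # pure translation
  out2 <- map_lesions(dets, list(A = sim_transform(1, 0, 50, 0)))
  expect_equal(as.numeric(out2[1, c("x0", "y0", "x1", "y1")]), c(60, 20, 90, 50))
  # unknown field errors
  expect_error(map_lesions(dets, list(B = st_identity())), "A")

  # same lesion from two overlapping fields merges to one
  dets2 <- rbind(dets,
                 data.frame(field_id = "B", type = 2L, x0 = -40, y0 = 21,
                            x1 = -10, y1 = 51, confidence = 0.8,
                            stringsAsFactors = FALSE))
  tr <- list(A = st_identity(), B = sim_transform(1, 0, 50, 0))
  out3 <- map_lesions(dets2, tr)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$confidence, 0.9)   # highest confidence wins
  expect_equal(out3$n_merged, 2L)

  # different types do not merge
  dets3 <- dets2; dets3$type[2] <- 3L
  expect_equal(nrow(map_lesions(dets3, tr)), 2)
})

test_that("duplicate merging is idempotent and equivariant under frame motion", {
  eye <- generate_eye(eye_config(lesion_probs = c(1, 1, 1, 1)), seed = 31)
  dets <- oracle_detector(eye)
  tr <- attr(eye$plan, "transforms")
  merged <- map_lesions(dets, tr)

  # idempotence: re-merging the merged output changes nothing
  again <- map_lesions(
    data.frame(field_id = "P", type = merged$type, x0 = merged$x0,
               y0 = merged$y0, x1 = merged$x1, y1 = merged$y1,
               confidence = merged$confidence, stringsAsFactors = FALSE),
    list(P = st_identity()))
  expect_equal(nrow(again), nrow(merged))
  expect_equal(again[, c("x0", "y0", "x1", "y1")],
               merged[, c("x0", "y0", "x1", "y1")], ignore_attr = TRUE)

  # equivariance: transforming the panorama frame transforms the output
  Tg <- sim_transform(1.3, 0.4, 100, -60)
  tr2 <- lapply(tr, function(t) st_compose(Tg, t))
  out2 <- map_lesions(dets, tr2)
  expect_equal(nrow(out2), nrow(merged))
  for (k in seq_len(nrow(merged))) {
    expect_equal(as.numeric(out2[k, c("x0", "y0", "x1", "y1")]),
                 st_map_box(Tg, as.numeric(merged[k, c("x0", "y0", "x1", "y1")])),
                 tolerance = 1e-9)
  }
})

test_that("a lesion seen in two fields with zero noise maps to one panorama lesion", {
  cfg <- eye_config(lesion_probs = c(0, 0, 1, 0), lesion_radius_range = c(280, 340))
  checked <- 0
  for (s in 1:40) {
    eye <- generate_eye(cfg, seed = 90000 + s)
    if (nrow(eye$lesions) != 1) next
    gt <- field_ground_truth(eye)
    if (length(unique(gt$field_id)) < 2) next
    out <- map_lesions(oracle_detector(eye), attr(eye$plan, "transforms"))
    expect_equal(nrow(out), 1)
    checked <- checked + 1
    if (checked >= 5) break
  }
  expect_gte(checked, 1)
})
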