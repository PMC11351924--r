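test_that("zone assignment follows the concentric template with inward boundaries", {
  f <- test_frame(d_df = 150, ora = 450)
  expect_equal(zone_of_point(f$disc_center, f), "I")
  # boundary points take the inner zone
  expect_equal(zone_of_point(f$disc_center + c(300, 0), f), "I")
  expect_equal(zone_of_point(f$disc_center + c(450, 0), f), "II")
  expect_equal(zone_of_point(f$disc_center + c(451, 0), f), "III")
  expect_equal(zone_of_point(f$disc_center + c(0, -301), f), "II")
  # the fovea always lies in zone I (r = d_df < 2 d_df)
  expect_equal(zone_of_point(f$fovea_center, f), "I")
})

test_that("zone index is radially monotone and scale equivariant", {
  f <- test_frame()
  set.seed(2)
  n <- 10000
  th <- runif(n, 0, 2 * pi); r <- runif(n, 0, 600)
  pts <- cbind(f$disc_center[1] + r * cos(th), f$disc_center[2] + r * sin(th))
  z <- match(zone_of_point(pts, f), c("I", "II", "III"))

  # monotone in r along any ray: checked by sorting within angle bins
  bins <- cut(th, 64)
  for (b in levels(bins)) {
    sel <- bins == b
    if (sum(sel) < 2) next
    o <- order(r[sel])
    expect_true(all(diff(z[sel][o]) >= 0))
  }

  # scaling all lengths and coordinates by lambda changes nothing
  for (lam in c(0.25, 3.7)) {
    f2 <- panorama_frame(f$disc_center * lam, f$fovea_center * lam,
                         f$ora_radius_nasal * lam, "OD")
    expect_equal(zone_of_point(pts * lam, f2), zone_of_point(pts, f))
  }
})

test_that("eye stage is the most severe lesion type, 0 when lesion-free", {
  expect_equal(eye_stage(integer()), 0L)
  expect_equal(eye_stage(c(1, 3, 2)), 3)
  expect_equal(eye_stage(4), 4)
  expect_error(eye_stage(c(1, 5)))
  expect_error(eye_stage(0))
})

test_that("eye zone follows the most severe lesion, not the most posterior overall", {
  f <- test_frame()
  mk <- function(type, r) {
    ctr <- f$disc_center + c(r, 0)
    data.frame(type = type, x0 = ctr[1] - 10, y0 = ctr[2] - 10,
               x1 = ctr[1] + 10, y1 = ctr[2] + 10)
  }
  expect_equal(eye_zone(NULL, f), "none")
  expect_equal(eye_zone(mk(3, 100), f), "I")
  # type-2 in zone I, type-3 in zone II: zone II (follows the type-3)
  les <- rbind(mk(2, 100), mk(3, 350))
  expect_equal(eye_zone(les, f), "II")
  # with the most-severe restriction off, the posterior-most lesion wins
  expect_equal(eye_zone(les, f, from_most_severe = FALSE), "I")
  # two maximal-type lesions in different zones: the more posterior wins
  les2 <- rbind(mk(3, 350), mk(3, 120))
  expect_equal(eye_zone(les2, f), "I")

  # permutation invariance
  set.seed(5)
  les3 <- rbind(mk(1, 90), mk(2, 320), mk(3, 460), mk(3, 200))
  for (i in 1:10) {
    p <- sample(nrow(les3))
    expect_equal(eye_zone(les3[p, ], f), eye_zone(les3, f))
    expect_equal(eye_stage(les3$type[p]), eye_stage(les3$type))
  }
})

test_that("generated lesions agree with the zoning module on their true zone", {
  total <- 0; i <- 0
  while (total < 500 && i < 2000) {
    i <- i + 1
    eye <- generate_eye(eye_config(), seed = 30000 + i)
    if (nrow(eye$lesions) == 0) next
    ctrs <- ropscreen:::lesion_centers(eye$lesions)
    expect_equal(zone_of_point(ctrs, eye$frame), eye$lesions$true_zone)
    total <- total + nrow(eye$lesions)
  }
  expect_gte(total, 500)
})

test_that("the overlay draws zone circles in increasing radius order", {
  f <- test_frame()
  pano <- matrix(0.1, 200, 200)
  ov <- render_zone_overlay(pano, f, origin = f$disc_center - c(100, 100))
  expect_equal(dim(ov), c(200, 200, 3))
  radii <- c(2 * f$d_df, f$ora_radius_nasal,
             max(f$ora_radius_nasal * 1.15, sqrt(2) * 100))
  expect_true(all(diff(radii) > 0))
  # disc marker present at the centre (cyan: green+blue high, red low)
  expect_gt(ov[100, 100, 3], 0.8)
})
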