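test_that("tortuosity index matches closed forms", {
  # straight segment
  expect_equal(tortuosity_index(rbind(c(0, 0), c(10, 0))), 1.0)
  # densely sampled semicircle: pi/2
  th <- seq(0, pi, length.out = 2000)
  semi <- cbind(cos(th), sin(th))
  expect_equal(tortuosity_index(semi), pi / 2, tolerance = 1e-3)
  # closed curve errors
  full <- cbind(cos(seq(0, 2 * pi, length.out = 100)),
                sin(seq(0, 2 * pi, length.out = 100)))
  expect_error(tortuosity_index(full), "chord")
})

test_that("tortuosity of a sinusoid matches the quadrature oracle and is monotone in amplitude", {
  lam <- 100
  sin_pts <- function(A, n = 1000) {
    x <- seq(0, lam, length.out = n)
    cbind(x, A * sin(2 * pi * x / lam))
  }
  # quadrature oracle: arc length of y = A sin(2 pi x / lambda)
  oracle <- function(A) {
    g <- function(x) sqrt(1 + (A * 2 * pi / lam * cos(2 * pi * x / lam))^2)
    stats::integrate(g, 0, lam, rel.tol = 1e-10)$value / lam
  }
  expect_equal(tortuosity_index(sin_pts(5)), oracle(5), tolerance = 1e-4)
  expect_equal(tortuosity_index(sin_pts(12)), oracle(12), tolerance = 1e-4)

  vals <- sapply(seq(0, 10, by = 0.5), function(A) tortuosity_index(sin_pts(A)))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("tortuosity is invariant to rigid motion and uniform scaling", {
  set.seed(6)
  x <- seq(0, 80, by = 0.5)
  pts <- cbind(x, 3 * sin(x / 7) + 0.5 * cos(x / 3))
  base <- tortuosity_index(pts)
  for (i in 1:10) {
    t <- sim_transform(runif(1, 0.1, 10), runif(1, -pi, pi),
                       runif(1, -100, 100), runif(1, -100, 100))
    expect_equal(tortuosity_index(st_apply(t, pts)), base, tolerance = 1e-9)
  }
})

test_that("centerline extraction recovers count, width and straightness", {
  # blank raster: nothing to trace
  expect_length(extract_centerlines(matrix(0.1, 100, 100)), 0)

  # one straight synthetic vessel of stroke width 4
  img <- matrix(0.1, 200, 300)
  img <- ropscreen:::draw_polyline(img, rbind(c(20, 100.3), c(280, 100.3)), 4, 0.55)
  img <- ropscreen:::draw_disk(img, c(10, 100), 8, 0.95)   # disc surrogate
  cls <- extract_centerlines(img, disc = c(10, 100), disc_radius = 10)
  expect_length(cls, 1)
  expect_lt(abs(mean(cls[[1]]$width_profile) - 4), 1)
  expect_lt(tortuosity_index(cls[[1]]$points), 1.005)

  # a full rendered disc-centred field: all 8 vessels traced
  eye <- generate_eye(eye_config(plus_prevalence = 0), seed = 14)
  rf <- render_fields(eye, fields = "F1")
  ff <- ropscreen:::field_frame(eye)
  cls8 <- extract_centerlines(rf$rasters[["F1"]], disc = ff$disc_center)
  expect_gte(length(cls8), 7)
  expect_lte(length(cls8), 10)
  # extracted widths near the generator's stroke width
  w <- mean(sapply(cls8, function(c) mean(c$width_profile)))
  expect_lt(abs(w - eye$vessel_width), 1.2)
})

test_that("the shipped calibration separates the generator's plus regimes", {
  cal <- ropscreen:::plus_default_calibration()
  expect_true(all(cal$coef >= 0))      # monotone score in both features
  expect_equal(cal$n, 200)

  # straight thin vessels: negative; generator plus regime: positive
  frame <- test_frame()
  straight <- lapply(1:8, function(i) {
    th <- i * pi / 4
    t <- seq(30, 300, by = 2)
    list(points = cbind(550 + t * cos(th), 550 + t * sin(th)), width = 3)
  })
  res_neg <- classify_plus(straight, frame)
  expect_false(res_neg$plus)

  wavy <- lapply(1:8, function(i) {
    th <- i * pi / 4; u <- c(cos(th), sin(th)); nv <- c(-sin(th), cos(th))
    t <- seq(30, 300, by = 2)
    disp <- 8 * sin(2 * pi * t / 120)
    list(points = cbind(550 + t * u[1] + disp * nv[1],
                        550 + t * u[2] + disp * nv[2]), width = 7)
  })
  res_pos <- classify_plus(wavy, frame)
  expect_true(res_pos$plus)
  expect_gt(res_pos$score, res_neg$score)

  # empty centerlines: indeterminate, distinct from negative
  res_na <- classify_plus(list())
  expect_true(is.na(res_na$plus))
  expect_true(is.na(res_na$score))
})

test_that("the plus score is monotone in tortuosity and width", {
  cal <- ropscreen:::plus_default_calibration()
  score <- function(tort, width) {
    z <- (c(tort, width) - cal$center) / cal$scale
    1 / (1 + exp(-(cal$intercept + sum(cal$coef * z))))
  }
  torts <- seq(1.0, 1.06, by = 0.005)
  expect_true(all(diff(sapply(torts, score, width = 4)) >= 0))
  widths <- seq(2, 8, by = 0.5)
  expect_true(all(diff(sapply(widths, function(w) score(1.01, w))) >= 0))
})

test_that("plus classification reaches 95% accuracy on a large balanced cohort", {
  # analytic centerlines (the generator's own vessel model) at n = 500
  cfg <- eye_config(plus_prevalence = 0.5)
  correct <- 0
  for (i in 1:500) {
    eye <- generate_eye(cfg, seed = 110000 + i)
    res <- classify_plus(vessel_centerlines(eye), eye$frame)
    correct <- correct + (isTRUE(res$plus) == eye$plus_present)
  }
  expect_gte(correct / 500, 0.95)
})

test_that("raster-based plus classification agrees with generator truth", {
  cfg <- eye_config(plus_prevalence = 0.5)
  for (i in 1:12) {
    eye <- generate_eye(cfg, seed = 120000 + i)
    rf <- render_fields(eye, fields = "F1")
    ff <- ropscreen:::field_frame(eye)
    cls <- extract_centerlines(rf$rasters[["F1"]], disc = ff$disc_center)
    res <- classify_plus(cls, ff)
    expect_equal(isTRUE(res$plus), eye$plus_present)
  }
})
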