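# Transparent plus-disease scorer: vessel centerlines are extracted from
# the disc-centred field, summarised by the two features plus disease is
# clinically defined by — tortuosity (arc/chord) and dilation (calibre) —
# restricted to zone I, and combined by a fixed logistic score whose
# coefficients were calibrated once on a seeded synthetic set and are
# shipped as a plain-text fixture (inst/extdata/plus_calibration.json).
# Nothing is refit at runtime.

shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Zhang-Suen thinning, vectorised over the whole image per sub-iteration.
skeletonize <- function(mask) {
  img <- matrix(as.numeric(mask), nrow(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(img, 1, 0);  p3 <- shift_mat(img, 1, -1)
      p4 <- shift_mat(img, 0, -1); p5 <- shift_mat(img, -1, -1)
      p6 <- shift_mat(img, -1, 0); p7 <- shift_mat(img, -1, 1)
      p8 <- shift_mat(img, 0, 1);  p9 <- shift_mat(img, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
        (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
      cond <- img == 1 & b >= 2 & b <= 6 & a == 1
      cond <- cond & if (sub == 1) (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { img[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1
}

# Vessel mask: the renderer draws vessels in a mid-intensity band,
# between the dark fundus background and the bright disc/lesion glyphs.
vessel_mask <- function(raster, band = c(0.3, 0.7)) {
  raster > band[1] & raster < band[2]
}

# Locate the optic disc as the centroid of the brightest blob.
find_disc <- function(raster, threshold = 0.85) {
  m <- raster >= threshold
  if (!any(m)) return(NULL)
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1,
    r = sqrt(sizes[big] / pi))
}

#' Extract vessel centerlines from a disc-centred field raster
#'
#' The vessel band is thresholded, skeletonised (Zhang-Suen thinning),
#' the optic disc neighbourhood removed, and each remaining connected
#' skeleton component traced outward from the disc by radial order.  The
#' local vessel width at each skeleton point is estimated from the
#' Euclidean distance transform of the vessel mask (width = 2 d - 1,
#' the pixel count across the stroke).  Components shorter than
#' `min_length` px are discarded as branch artifacts.
#'
#' @param raster grayscale disc-centred field.
#' @param disc optional `c(x, y)` disc centre in field px (found from the
#'   brightest blob when omitted).
#' @param disc_radius radius around the disc to exclude from tracing.
#' @param min_length minimum traced length in px.
#' @return A list of centerlines, each a list with `points` (n x 2, field
#'   px, ordered from the disc outward) and `width_profile` (per-point
#'   widths, px).  Empty list when no vessels are found.
#' @export
extract_centerlines <- function(raster, disc = NULL, disc_radius = 34,
                                min_length = 20) {
  mask <- vessel_mask(raster)
  if (!any(mask)) return(list())
  if (is.null(disc)) {
    d <- find_disc(raster)
    if (is.null(d)) return(list())
    disc <- d[c("x", "y")]
    disc_radius <- max(disc_radius, d[["r"]] + 3)
  }
  dist <- EBImage::distmap(mask)
  skel <- skeletonize(mask)
  xs <- matrix(rep(0:(ncol(raster) - 1), each = nrow(raster)), nrow(raster))
  ys <- matrix(rep(0:(nrow(raster) - 1), times = ncol(raster)), nrow(raster))
  rr <- sqrt((xs - disc[1])^2 + (ys - disc[2])^2)
  skel[rr <= disc_radius] <- FALSE
  if (!any(skel)) return(list())
  # label with 8-connectivity: dilate by one pixel so diagonal links touch,
  # label, then restrict labels to the skeleton (vessels are farther apart
  # than the dilation radius, so distinct vessels stay distinct)
  big <- EBImage::dilate(matrix(as.numeric(skel), nrow(skel)),
                         matrix(1, 3, 3))
  lab <- EBImage::bwlabel(big) * skel
  out <- list()
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp)
    if (length(idx) < 2) next
    o <- order(rr[idx])
    pts <- cbind(xs[idx][o], ys[idx][o])
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    if (sum(seg) < min_length) next
    sm <- smooth_chain(pts, window = 9, stride = 3)
    out[[length(out) + 1]] <- list(
      points = sm$points,
      width_profile = (2 * dist[idx][o] - 0.5)[sm$index])
  }
  out
}

# Moving-average smoothing of a traced pixel chain followed by
# subsampling.  A digital line visited pixel-by-pixel is a staircase
# whose polygonal length overestimates the underlying curve's; averaging
# over a window much shorter than the vessel wavelength removes the
# staircase while leaving genuine tortuosity intact.
smooth_chain <- function(pts, window = 9, stride = 3) {
  n <- nrow(pts)
  if (n <= 2) return(list(points = pts, index = seq_len(n)))
  half <- floor(window / 2)
  cs <- rbind(c(0, 0), apply(pts, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1); hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  idx <- unique(c(seq(1, n, by = stride), n))
  list(points = sm[idx, , drop = FALSE], index = idx)
}

#' Arc-over-chord tortuosity index of a centerline
#'
#' Polyline arc length divided by the straight-line distance between the
#' endpoints; 1.0 for a straight vessel, larger for tortuous ones.
#' Invariant to rigid motion and uniform scaling.
#'
#' @param points n x 2 matrix of ordered centerline points (n >= 2), or a
#'   centerline list with a `points` field.
#' @return Tortuosity index >= 1 (up to sampling error).
#' @export
tortuosity_index <- function(points) {
  if (is.list(points) && !is.null(points$points)) points <- points$points
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 2)
  seg <- sqrt(diff(points[, 1])^2 + diff(points[, 2])^2)
  if (any(seg == 0)) points <- points[c(TRUE, seg > 0), , drop = FALSE]
  arc <- sum(sqrt(diff(points[, 1])^2 + diff(points[, 2])^2))
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (chord < 1e-9) stop("zero chord: closed or degenerate centerline")
  arc / chord
}

plus_default_calibration <- function() {
  path <- system.file("extdata", "plus_calibration.json", package = "ropscreen")
  if (path == "") stop("plus calibration fixture not found")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

plus_features_from_centerlines <- function(centerlines, frame = NULL) {
  if (!is.null(frame)) {
    centerlines <- lapply(centerlines, function(cl) {
      inz <- zone_of_point(cl$points, frame) == "I"
      keep <- which(inz)
      if (length(keep) < 2) return(NULL)
      list(points = cl$points[keep, , drop = FALSE],
           width_profile = if (!is.null(cl$width_profile))
             cl$width_profile[keep] else rep(cl$width, length(keep)))
    })
    centerlines <- Filter(Negate(is.null), centerlines)
  } else {
    centerlines <- lapply(centerlines, function(cl) {
      if (is.null(cl$width_profile))
        cl$width_profile <- rep(cl$width, nrow(cl$points))
      cl
    })
  }
  if (length(centerlines) == 0) return(NULL)
  torts <- vapply(centerlines, function(cl) tortuosity_index(cl$points), 0)
  widths <- vapply(centerlines, function(cl) mean(cl$width_profile), 0)
  list(mean_tortuosity = mean(torts), max_tortuosity = max(torts),
       mean_width = mean(widths))
}

#' Classify plus disease from vessel centerlines
#'
#' Features (mean tortuosity, mean width) are computed on the centerline
#' portions inside zone I, standardised with the shipped calibration
#' statistics, and combined by a logistic score with fixed non-negative
#' coefficients; `plus = score >= 0.5`.  An empty centerline list yields
#' an indeterminate result (`plus = NA`), which downstream treats as
#' distinct from a negative call.
#'
#' @param centerlines list of centerlines (`points` + `width_profile` or
#'   scalar `width`), in the same frame as `frame`.
#' @param frame a [panorama_frame()] used for the zone I restriction;
#'   `NULL` disables the restriction.
#' @param calibration calibration list (`coef`, `center`, `scale`);
#'   defaults to the shipped fixture.
#' @param threshold decision threshold on the score.
#' @return List of class `plus_result`: `score` in [0, 1] (`NA` when
#'   indeterminate), `plus` (logical or `NA`), `features`.
#' @export
classify_plus <- function(centerlines, frame = NULL,
                          calibration = plus_default_calibration(),
                          threshold = 0.5) {
  feats <- plus_features_from_centerlines(centerlines, frame)
  if (is.null(feats))
    return(structure(list(score = NA_real_, plus = NA,
                          features = list(mean_tortuosity = NA_real_,
                                          max_tortuosity = NA_real_,
                                          mean_width = NA_real_)),
                     class = "plus_result"))
  x <- c(feats$mean_tortuosity, feats$mean_width)
  z <- (x - calibration$center) / calibration$scale
  eta <- calibration$intercept + sum(calibration$coef * z)
  score <- 1 / (1 + exp(-eta))
  structure(list(score = score, plus = score >= threshold, features = feats),
            class = "plus_result")
}

#' @export
print.plus_result <- function(x, ...) {
  cat(sprintf("<plus_result score=%.3f plus=%s (tort=%.4f width=%.2f)>\n",
              x$score, x$plus, x$features$mean_tortuosity,
              x$features$mean_width))
  invisible(x)
}

#' Calibrate the plus logistic score on synthetic disc-centred fields
#'
#' Renders `n` synthetic eyes with balanced plus classes, extracts
#' centerlines from each disc-centred field, computes the zone I
#' features, and fits a ridge-regularised logistic regression
#' (`glmnet`, alpha = 0) of plus status on the standardised features.
#' The small ridge penalty keeps coefficients finite (the default
#' regimes are linearly separable) while preserving the sign structure;
#' both coefficients are required to come out non-negative, which
#' guarantees the score is monotone in tortuosity and in width.
#'
#' This is how the shipped fixture was produced (n = 200, seed = 2024);
#' it is exported so the calibration is reproducible, but the classifier
#' never refits at runtime.
#'
#' @param n number of calibration eyes (half plus, half not).
#' @param seed integer seed.
#' @param config generator configuration.
#' @param lambda ridge penalty.
#' @return Calibration list: `intercept`, `coef` (length 2:
#'   mean_tortuosity, mean_width), `center`, `scale`, `n`, `seed`,
#'   `train_accuracy`.
#' @export
calibrate_plus_model <- function(n = 200, seed = 2024, config = eye_config(),
                                 lambda = 0.05) {
  stopifnot(n %% 2 == 0)
  y <- rep(c(FALSE, TRUE), n / 2)
  feats <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$plus_prevalence <- as.numeric(y[i])    # force the class
    cfg$lesion_probs[] <- cfg$lesion_probs     # lesions irrelevant here
    eye <- generate_eye(cfg, seed = derive_seed(seed, i),
                        eye_id = sprintf("cal%04d", i))
    rf <- render_fields(eye, fields = "F1")
    frame_f <- field_frame(eye)
    cls <- extract_centerlines(rf$rasters[["F1"]],
                               disc = frame_f$disc_center,
                               disc_radius = config$disc_radius + 4)
    f <- plus_features_from_centerlines(cls, frame_f)
    if (!is.null(f)) feats[i, ] <- c(f$mean_tortuosity, f$mean_width)
  }
  ok <- stats::complete.cases(feats)
  ctr <- colMeans(feats[ok, ]); scl <- apply(feats[ok, , drop = FALSE], 2, stats::sd)
  z <- scale(feats[ok, ], center = ctr, scale = scl)
  fit <- glmnet::glmnet(z, factor(y[ok]), family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  beta <- as.numeric(fit$beta)
  cal <- list(intercept = as.numeric(fit$a0), coef = beta,
              center = as.numeric(ctr), scale = as.numeric(scl),
              feature_names = c("mean_tortuosity", "mean_width"),
              n = sum(ok), seed = seed)
  eta <- cal$intercept + z %*% beta
  cal$train_accuracy <- mean((eta > 0) == y[ok])
  cal
}

# Frame of the eye expressed in the disc-centred field's coordinates
# (the anchor field: panorama coordinates inherit this frame).
field_frame <- function(eye, field_id = "F1") {
  inv <- st_inverse(plan_transform(eye$plan, field_id))
  panorama_frame(st_apply(inv, eye$disc_center),
                 st_apply(inv, eye$fovea_center),
                 eye$ora_radius_nasal, eye$laterality)
}
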