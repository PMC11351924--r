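#' Configuration for the synthetic-eye generator
#'
#' The generator emulates the structure of a wide-field digital retinal
#' imaging (RetCam-style) screening exam: one eye imaged as several
#' overlapping 640 x 480 orientation fields related to a per-eye panorama
#' by known similarity transforms, with a bright optic disc, vessels
#' radiating from the disc whose tortuosity and calibre encode plus
#' disease, and type-coded lesion glyphs at known panoramic positions.
#' All geometry is in panorama pixels at a fixed anatomical scale of
#' disc diameter = 60 px.
#'
#' Default plus-disease regimes keep the two classes physiologically
#' distinct: normal vessels have sinusoid amplitude 0-1.5 px and stroke
#' width 3-4 px; plus vessels 4-8 px amplitude and 5-7 px width.
#'
#' @param lesion_probs named numeric: probability that a lesion of each
#'   type 1-4 is present in an eye.
#' @param plus_prevalence probability that an eye has plus disease.
#' @param laterality_probs probabilities for OD/OS.
#' @param d_df_range range of the disc-fovea distance (px).
#' @param ora_radius disc-to-nasal-ora distance (px); must exceed twice
#'   the largest disc-fovea distance.
#' @param disc_radius optic disc radius (px).
#' @param retina_radius rendered retinal extent (px from disc).
#' @param lesion_extent_range range of lesion box side lengths (px).
#' @param lesion_radius_range radial range for lesion centres (px from
#'   disc).
#' @param amp_normal,amp_plus tortuosity amplitude ranges (px).
#' @param width_normal,width_plus vessel stroke width ranges (px).
#' @param n_vessels number of vessel centerlines leaving the disc.
#' @param vessel_wavelength sinusoid wavelength along the vessel (px).
#' @param field_size c(width, height) of each field raster.
#' @param field_offset offset of the peripheral fields from the disc (px).
#' @param canvas c(width, height) of the panorama canvas.
#' @param background_noise sd of optional additive Gaussian raster noise.
#' @return A list of class `eye_config`.
#' @export
eye_config <- function(lesion_probs = c(`1` = 0.35, `2` = 0.30, `3` = 0.20, `4` = 0.08),
                       plus_prevalence = 0.25,
                       laterality_probs = c(OD = 0.5, OS = 0.5),
                       d_df_range = c(145, 155),
                       ora_radius = 450,
                       disc_radius = 30,
                       retina_radius = 510,
                       lesion_extent_range = c(30, 64),
                       lesion_radius_range = c(70, 500),
                       amp_normal = c(0, 1.5), amp_plus = c(4, 8),
                       width_normal = c(3, 4), width_plus = c(5, 7),
                       n_vessels = 8, vessel_wavelength = 120,
                       field_size = c(640, 480), field_offset = 300,
                       canvas = c(1100, 1100),
                       background_noise = 0) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$lesion_probs) == 4, all(cfg$lesion_probs >= 0),
            all(cfg$lesion_probs <= 1))
  if (is.null(names(cfg$lesion_probs))) names(cfg$lesion_probs) <- as.character(1:4)
  if (cfg$ora_radius <= 2 * max(cfg$d_df_range))
    stop("infeasible geometry: ora_radius must exceed twice the disc-fovea distance")
  structure(cfg, class = "eye_config")
}

#' Camera plan: field specifications for one eye
#'
#' The default 5-field plan mirrors a standard screening capture: one
#' disc-centred field plus nasal, temporal, superior and inferior fields
#' offset from the disc, each related to the panorama by a pure
#' translation (the contact camera is re-oriented, not rotated, between
#' shots; the registration module itself supports scale and rotation).
#' Adjacent fields overlap by well over 25% of their area.
#'
#' @param eye a `ground_truth_eye` (for disc position and laterality);
#'   alternatively supply `disc_center` and `laterality` directly.
#' @param config an [eye_config()].
#' @param disc_center,laterality used when `eye` is `NULL`.
#' @return A data frame with `field_id`, `orientation_label`, transform
#'   parameter columns and a `transforms` attribute (named list of
#'   `sim_transform`, field to panorama).
#' @export
default_field_plan <- function(eye = NULL, config = eye_config(),
                               disc_center = NULL, laterality = NULL) {
  if (!is.null(eye)) { disc_center <- eye$disc_center; laterality <- eye$laterality }
  fs <- config$field_size
  fc <- fs / 2
  off <- config$field_offset
  nasal_sign <- if (laterality == "OD") 1 else -1
  offs <- list(disc_centered = c(0, 0),
               nasal = c(nasal_sign * off, 0),
               temporal = c(-nasal_sign * off, 0),
               superior = c(0, -off),
               inferior = c(0, off))
  transforms <- lapply(offs, function(d) {
    t <- disc_center + d - fc
    sim_transform(1, 0, t[1], t[2])
  })
  plan <- data.frame(field_id = paste0("F", seq_along(offs)),
                     orientation_label = names(offs),
                     width = fs[1], height = fs[2],
                     stringsAsFactors = FALSE)
  names(transforms) <- plan$field_id
  attr(plan, "transforms") <- transforms
  plan
}

plan_transform <- function(plan, field_id) attr(plan, "transforms")[[field_id]]

# Is a panorama-space box fully visible in at least one field?
box_covered <- function(plan, box) {
  tr <- attr(plan, "transforms")
  for (i in seq_len(nrow(plan))) {
    inv <- st_inverse(tr[[plan$field_id[i]]])
    b <- st_map_box(inv, box)
    if (b[1] >= 0 && b[2] >= 0 && b[3] <= plan$width[i] && b[4] <= plan$height[i])
      return(TRUE)
  }
  FALSE
}

#' Generate a ground-truth eye
#'
#' Draws laterality, geometry, plus status, vessel parameters and lesions
#' from the configured distributions.  Lesion centres are rejection-
#' sampled so that every lesion box is fully visible in at least one
#' field of the camera plan (a screening exam images the clinically
#' assessable retina).  Each lesion's `true_zone` is computed from the
#' eye's own [panorama_frame()] via [zone_of_point()], so generator and
#' zoning module are self-consistent by construction.
#'
#' Identical `(config, seed)` reproduce an identical eye; the caller's
#' RNG state is untouched.
#'
#' @param config an [eye_config()].
#' @param seed integer seed.
#' @param eye_id identifier string.
#' @return An object of class `ground_truth_eye`: fields `eye_id`,
#'   `laterality`, `disc_center`, `fovea_center`, `ora_radius_nasal`,
#'   `frame`, `plan`, `lesions` (data frame), `plus_present`,
#'   `tortuosity_amp`, `vessel_width`, `vessel_angles`, `vessel_phases`,
#'   `seed`, `config`.
#' @export
generate_eye <- function(config = eye_config(), seed = 1, eye_id = sprintf("eye%05d", seed)) {
  stopifnot(inherits(config, "eye_config"))
  with_seed(seed, {
    laterality <- sample(names(config$laterality_probs), 1,
                         prob = config$laterality_probs)
    d_df <- runif1(config$d_df_range)
    disc <- config$canvas / 2
    nasal <- if (laterality == "OD") c(1, 0) else c(-1, 0)
    fovea <- disc - d_df * nasal
    frame <- panorama_frame(disc, fovea, config$ora_radius, laterality)
    plan <- default_field_plan(disc_center = disc, laterality = laterality,
                               config = config)

    plus_present <- stats::runif(1) < config$plus_prevalence
    amp <- runif1(if (plus_present) config$amp_plus else config$amp_normal)
    vw <- runif1(if (plus_present) config$width_plus else config$width_normal)
    angles <- seq(0, 2 * pi, length.out = config$n_vessels + 1)[-(config$n_vessels + 1)] +
      stats::runif(1, 0, 2 * pi / config$n_vessels)
    phases <- stats::runif(config$n_vessels, 0, 2 * pi)

    les <- list()
    for (type in 1:4) {
      if (stats::runif(1) < config$lesion_probs[[as.character(type)]]) {
        for (try in 1:200) {
          r <- runif1(config$lesion_radius_range)
          th <- stats::runif(1, 0, 2 * pi)
          ctr <- disc + r * c(cos(th), sin(th))
          w <- runif1(config$lesion_extent_range)
          h <- runif1(config$lesion_extent_range)
          box <- c(ctr - c(w, h) / 2, ctr + c(w, h) / 2)
          if (r <= config$retina_radius - max(w, h) / 2 && box_covered(plan, box)) {
            les[[length(les) + 1]] <- data.frame(
              lesion_id = sprintf("%s_L%d", eye_id, length(les) + 1),
              type = type, x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4],
              true_zone = zone_of_point(ctr, frame), stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    lesions <- if (length(les)) do.call(rbind, les) else
      data.frame(lesion_id = character(), type = integer(), x0 = numeric(),
                 y0 = numeric(), x1 = numeric(), y1 = numeric(),
                 true_zone = character(), stringsAsFactors = FALSE)

    structure(list(eye_id = eye_id, laterality = laterality,
                   disc_center = disc, fovea_center = fovea,
                   ora_radius_nasal = config$ora_radius, frame = frame,
                   plan = plan, lesions = lesions, plus_present = plus_present,
                   tortuosity_amp = amp, vessel_width = vw,
                   vessel_angles = angles, vessel_phases = phases,
                   seed = seed, config = config),
              class = "ground_truth_eye")
  })
}

#' @export
print.ground_truth_eye <- function(x, ...) {
  cat(sprintf("<ground_truth_eye %s %s: %d lesion(s), plus=%s, amp=%.1f, width=%.1f>\n",
              x$eye_id, x$laterality, nrow(x$lesions), x$plus_present,
              x$tortuosity_amp, x$vessel_width))
  invisible(x)
}

#' Analytic vessel centerlines of a generated eye
#'
#' Each vessel is a ray from the disc rim to the retinal extent with a
#' sinusoidal displacement along the ray normal: at arc parameter
#' \eqn{t}, displacement \eqn{A \sin(2\pi t/\lambda + \phi)}.
#'
#' @param eye a `ground_truth_eye`.
#' @param step sampling step along the ray (px).
#' @return A list of centerlines: each a list with `points` (n x 2
#'   matrix, panorama px) and `width` (scalar stroke width).
#' @export
vessel_centerlines <- function(eye, step = 2) {
  cfg <- eye$config
  lapply(seq_along(eye$vessel_angles), function(i) {
    th <- eye$vessel_angles[i]; ph <- eye$vessel_phases[i]
    u <- c(cos(th), sin(th)); nvec <- c(-sin(th), cos(th))
    t <- seq(cfg$disc_radius, cfg$retina_radius, by = step)
    disp <- eye$tortuosity_amp * sin(2 * pi * t / cfg$vessel_wavelength + ph)
    pts <- cbind(eye$disc_center[1] + t * u[1] + disp * nvec[1],
                 eye$disc_center[2] + t * u[2] + disp * nvec[2])
    list(points = pts, width = eye$vessel_width)
  })
}

draw_lesion_glyph <- function(img, type, box) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  val <- 0.82
  if (type == 1) {                       # demarcation line
    img <- draw_polyline(img, rbind(c(box[1] + 2, cy), c(box[3] - 2, cy)), 3, val)
  } else if (type == 2) {                # ridge: thick arc
    th <- seq(pi * 0.15, pi * 0.85, length.out = 40)
    pts <- cbind(cx + (w / 2 - 2) * cos(th), cy + (h / 2 - 2) * sin(th))
    img <- draw_polyline(img, pts, 4, val)
  } else if (type == 3) {                # ridge + extraretinal proliferation
    th <- seq(pi * 0.15, pi * 0.85, length.out = 40)
    pts <- cbind(cx + (w / 2 - 2) * cos(th), cy + (h / 2 - 2) * sin(th))
    img <- draw_polyline(img, pts, 4, val)
    dots <- cbind(cx + (w / 4) * cos(seq(0, 2 * pi, length.out = 7)),
                  cy - h / 6 + (h / 6) * sin(seq(0, 2 * pi, length.out = 7)))
    img <- stamp_points(img, dots, 2, 0.9)
  } else {                               # detachment: filled wedge
    tri <- rbind(c(cx, box[2] + 2), c(box[1] + 2, box[4] - 2),
                 c(box[3] - 2, box[4] - 2))
    for (f in seq(0, 1, by = 0.08)) {
      apex <- tri[1, ]
      base <- rbind(apex + f * (tri[2, ] - apex), apex + f * (tri[3, ] - apex))
      img <- draw_polyline(img, base, 2.5, 0.88)
    }
  }
  img
}

#' Render the panoramic scene of a ground-truth eye
#'
#' Deterministic given the eye: dark background with a smooth texture,
#' brighter retinal disk out to the rendered extent, a dark foveal spot,
#' the bright optic disc, vessels at the eye's tortuosity amplitude and
#' stroke width (mid-intensity band), and one type-coded high-contrast
#' glyph per lesion.  Glyphs are schematic, not photorealistic: the
#' pipeline consumes detections, and the rasters only need to support
#' registration and vessel extraction.
#'
#' @param eye a `ground_truth_eye`.
#' @return Grayscale panorama matrix (canvas size from the config).
#' @export
render_eye_panorama <- function(eye) {
  cfg <- eye$config
  w <- cfg$canvas[1]; h <- cfg$canvas[2]
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  img <- 0.08 + 0.02 * sin(2 * pi * xs / 173) * sin(2 * pi * ys / 211) +
    0.015 * sin(2 * pi * (xs + ys) / 97)
  rr <- sqrt((xs - eye$disc_center[1])^2 + (ys - eye$disc_center[2])^2)
  img[rr <= cfg$retina_radius] <- img[rr <= cfg$retina_radius] + 0.05
  for (cl in vessel_centerlines(eye))
    img <- draw_polyline(img, cl$points, cl$width, 0.55)
  img <- draw_disk(img, eye$fovea_center, 8, 0.04)
  img <- draw_disk(img, eye$disc_center, cfg$disc_radius, 0.95)
  if (nrow(eye$lesions) > 0)
    for (i in seq_len(nrow(eye$lesions)))
      img <- draw_lesion_glyph(img, eye$lesions$type[i],
                               as.numeric(eye$lesions[i, c("x0", "y0", "x1", "y1")]))
  img
}

#' Per-field lesion ground truth
#'
#' For every lesion whose panoramic box intersects a field, the box is
#' mapped through the inverse field transform (axis-aligned hull of the
#' mapped corners) and clipped to the raster.
#'
#' @param eye a `ground_truth_eye`.
#' @param plan camera plan; defaults to the eye's own.
#' @return Data frame: `field_id`, `lesion_id`, `type`, `x0`, `y0`,
#'   `x1`, `y1` (field px, clipped), `clipped` flag.
#' @export
field_ground_truth <- function(eye, plan = eye$plan) {
  out <- list()
  tr <- attr(plan, "transforms")
  for (i in seq_len(nrow(plan))) {
    fid <- plan$field_id[i]
    inv <- st_inverse(tr[[fid]])
    for (j in seq_len(nrow(eye$lesions))) {
      b <- st_map_box(inv, as.numeric(eye$lesions[j, c("x0", "y0", "x1", "y1")]))
      cb <- c(clamp(b[1], 0, plan$width[i]), clamp(b[2], 0, plan$height[i]),
              clamp(b[3], 0, plan$width[i]), clamp(b[4], 0, plan$height[i]))
      if (cb[3] > cb[1] && cb[4] > cb[2])
        out[[length(out) + 1]] <- data.frame(
          field_id = fid, lesion_id = eye$lesions$lesion_id[j],
          type = eye$lesions$type[j],
          x0 = cb[1], y0 = cb[2], x1 = cb[3], y1 = cb[4],
          clipped = any(abs(cb - b) > 1e-9), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(field_id = character(), lesion_id = character(), type = integer(),
               x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
               clipped = logical(), stringsAsFactors = FALSE)
}

#' Render the orientation fields of an eye
#'
#' Renders the panorama once and warps each field out of it through the
#' inverse of its field-to-panorama transform.  Also returns the
#' per-field ground-truth boxes and a generation report; a lesion visible
#' in no field is recorded as a warning in the report.
#'
#' @param eye a `ground_truth_eye`.
#' @param plan camera plan; defaults to the eye's own.
#' @param noise_sd optional additive Gaussian noise sd (seeded from the
#'   eye's seed); 0 disables.
#' @param fields optional character vector restricting which fields to
#'   render (ground truth is still computed for the full plan).
#' @return List with `rasters` (named list of matrices), `ground_truth`
#'   (data frame from [field_ground_truth()]), `panorama`, and `report`
#'   (data frame of generation warnings, possibly empty).
#' @export
render_fields <- function(eye, plan = eye$plan, noise_sd = eye$config$background_noise,
                          fields = plan$field_id) {
  pano <- render_eye_panorama(eye)
  tr <- attr(plan, "transforms")
  rasters <- list()
  for (i in seq_len(nrow(plan))) {
    fid <- plan$field_id[i]
    if (!fid %in% fields) next
    rasters[[fid]] <- warp_raster(pano, st_inverse(tr[[fid]]),
                                  plan$width[i], plan$height[i])
  }
  if (noise_sd > 0) {
    rasters <- with_seed(derive_seed(eye$seed, 555), lapply(rasters, function(r)
      clamp(r + matrix(stats::rnorm(length(r), 0, noise_sd), nrow(r)), 0, 1)))
  }
  gt <- field_ground_truth(eye, plan)
  missing <- setdiff(eye$lesions$lesion_id, gt$lesion_id)
  report <- if (length(missing))
    data.frame(eye_id = eye$eye_id, lesion_id = missing,
               warning = "lesion visible in no field", stringsAsFactors = FALSE)
  else data.frame(eye_id = character(), lesion_id = character(),
                  warning = character(), stringsAsFactors = FALSE)
  list(rasters = rasters, ground_truth = gt, panorama = pano, report = report)
}
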