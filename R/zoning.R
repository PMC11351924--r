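#' Per-eye panoramic coordinate frame for ICROP zone geometry
#'
#' The zone templates are concentric circles centred on the optic disc:
#' zone I is the disc-centred circle of radius twice the disc-fovea
#' distance, zone II extends to the disc-centred circle through the nasal
#' ora serrata, and zone III is the residual retina beyond that circle
#' (the nasal cut-off where zone III is anatomically absent is not
#' modelled).  Laterality fixes the mirror convention: the nasal direction
#' is +x for a right eye (OD) and -x for a left eye (OS), with the fovea
#' temporal to the disc.
#'
#' @param disc_center,fovea_center 2-D points in panorama pixels.
#' @param ora_radius_nasal distance from the disc to the nasal ora
#'   serrata, panorama pixels; must exceed twice the disc-fovea distance
#'   so that zone II strictly contains zone I.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @return An object of class `panorama_frame` with fields `disc_center`,
#'   `fovea_center`, `nasal_unit`, `ora_radius_nasal`, `laterality` and
#'   the derived disc-fovea distance `d_df`.
#' @export
panorama_frame <- function(disc_center, fovea_center, ora_radius_nasal,
                           laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  disc_center <- as.numeric(disc_center); fovea_center <- as.numeric(fovea_center)
  d_df <- sqrt(sum((fovea_center - disc_center)^2))
  if (d_df <= 0) stop("disc-fovea distance must be positive")
  nasal_unit <- if (laterality == "OD") c(1, 0) else c(-1, 0)
  if (sum(nasal_unit * (fovea_center - disc_center)) >= 0)
    stop("fovea must be temporal to the disc for laterality ", laterality)
  if (ora_radius_nasal <= 2 * d_df)
    stop("ora_radius_nasal must exceed twice the disc-fovea distance")
  structure(list(disc_center = disc_center, fovea_center = fovea_center,
                 nasal_unit = nasal_unit, ora_radius_nasal = ora_radius_nasal,
                 laterality = laterality, d_df = d_df),
            class = "panorama_frame")
}

#' Assign a point to an ICROP zone
#'
#' With \eqn{r} the distance from the point to the disc centre and
#' \eqn{d} the disc-fovea distance: zone I if \eqn{r \le 2d}, zone II if
#' \eqn{r \le} the nasal ora radius, zone III otherwise.  Points exactly
#' on a boundary take the inner (more posterior, more severe) zone — the
#' conservative choice for screening.
#'
#' @param p a length-2 point or an n x 2 matrix of points (panorama px).
#' @param frame a [panorama_frame()].
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @examples
#' f <- panorama_frame(c(0, 0), c(-150, 0), 450, "OD")
#' zone_of_point(c(0, 0), f)    # "I"
#' zone_of_point(c(300, 0), f)  # boundary resolves inward: "I"
#' @export
zone_of_point <- function(p, frame) {
  stopifnot(inherits(frame, "panorama_frame"))
  if (is.null(dim(p))) p <- matrix(p, 1, 2)
  r <- sqrt((p[, 1] - frame$disc_center[1])^2 + (p[, 2] - frame$disc_center[2])^2)
  ifelse(r <= 2 * frame$d_df, "I",
         ifelse(r <= frame$ora_radius_nasal, "II", "III"))
}

#' Stage of an eye from its panoramic lesion list
#'
#' The stage is the type of the most severe lesion present (1 demarcation
#' line, 2 ridge, 3 ridge with extraretinal fibrovascular proliferation,
#' 4 subtotal retinal detachment); an eye with no lesions is stage 0.
#'
#' @param lesions a lesion data frame (see [map_lesions()]) or a vector of
#'   lesion types.
#' @return Integer stage 0-4.
#' @export
eye_stage <- function(lesions) {
  types <- if (is.data.frame(lesions)) lesions$type else lesions
  if (length(types) == 0) return(0L)
  types <- as.integer(types)
  if (any(is.na(types)) || any(types < 1L | types > 4L))
    stop("lesion types must be integers in 1..4")
  max(types)
}

#' Zone of an eye from its panoramic lesion list
#'
#' Zoning follows the most severe lesion: among lesions of maximal type,
#' the zone of each lesion centre is computed and the most posterior zone
#' (I < II < III) is returned, so that disagreement between equally severe
#' lesions resolves toward the more severe call.  An eye with no lesions
#' has zone `"none"`.
#'
#' @param lesions lesion data frame with columns `type`, `x0`, `y0`,
#'   `x1`, `y1` (panorama px, half-open boxes).
#' @param frame a [panorama_frame()].
#' @param from_most_severe if `FALSE`, zone is instead taken over all
#'   lesions regardless of type (the most posterior lesion overall).
#' @return One of `"I"`, `"II"`, `"III"`, `"none"`.
#' @export
eye_zone <- function(lesions, frame, from_most_severe = TRUE) {
  if (is.null(lesions) || nrow(lesions) == 0) return("none")
  sel <- if (from_most_severe) lesions$type == max(lesions$type) else TRUE
  sub <- lesions[sel, , drop = FALSE]
  centers <- cbind((sub$x0 + sub$x1) / 2, (sub$y0 + sub$y1) / 2)
  zones <- zone_of_point(centers, frame)
  c("I", "II", "III")[min(match(zones, c("I", "II", "III")))]
}

lesion_centers <- function(lesions) {
  cbind((lesions$x0 + lesions$x1) / 2, (lesions$y0 + lesions$y1) / 2)
}

#' Render the interpretability overlay for an assessed eye
#'
#' Draws the zone I and zone II boundary circles, an outer render bound,
#' disc and fovea markers, each lesion's panoramic box labelled with its
#' type digit, and returns the annotated RGB raster.  This is the visual
#' evidence surface a clinician reviews alongside the severity call.
#'
#' @param panorama grayscale panorama matrix.
#' @param frame a [panorama_frame()]; coordinates must be in the panorama
#'   raster frame (use `origin` to shift if the montage was re-anchored).
#' @param lesions lesion data frame (may be empty or `NULL`).
#' @param assessment optional assessment list (adds a severity tick mark).
#' @param origin 2-D offset of the raster's (0, 0) in frame coordinates.
#' @return An h x w x 3 RGB array in [0, 1].
#' @export
render_zone_overlay <- function(panorama, frame, lesions = NULL,
                                assessment = NULL, origin = c(0, 0)) {
  rgb <- gray_to_rgb(panorama)
  dc <- frame$disc_center - origin
  fc <- frame$fovea_center - origin
  red <- c(1, 0.15, 0.15); purple <- c(0.7, 0.3, 0.9); green <- c(0.2, 0.9, 0.3)
  yellow <- c(1, 0.9, 0.1); cyan <- c(0.2, 0.9, 0.9)
  outer_r <- max(frame$ora_radius_nasal * 1.15,
                 sqrt(sum(raster_size(panorama)^2)) / 2)
  rgb <- rgb_draw(rgb, draw_circle, red, center = dc, radius = 2 * frame$d_df)
  rgb <- rgb_draw(rgb, draw_circle, purple, center = dc,
                  radius = frame$ora_radius_nasal)
  rgb <- rgb_draw(rgb, draw_circle, green, center = dc, radius = outer_r)
  rgb <- rgb_draw(rgb, draw_disk, cyan, center = dc, radius = 4)
  rgb <- rgb_draw(rgb, draw_disk, cyan, center = fc, radius = 3)
  if (!is.null(lesions) && nrow(lesions) > 0) {
    for (i in seq_len(nrow(lesions))) {
      box <- as.numeric(lesions[i, c("x0", "y0", "x1", "y1")]) - c(origin, origin)
      rgb <- rgb_draw(rgb, draw_box_outline, yellow, box = box)
      rgb <- rgb_draw(rgb, draw_digit, yellow, digit = lesions$type[i],
                      origin = c(box[1] + 2, box[2] + 2))
    }
  }
  if (!is.null(assessment) && identical(assessment$severity, "severe"))
    rgb <- rgb_draw(rgb, draw_disk, red, center = c(10, 10), radius = 6)
  rgb
}
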