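#' Write and read COCO-style annotations for an eye
#'
#' The annotation dialect follows the COCO object-detection layout —
#' `images` (with `id`, `file_name`, `width`, `height`), `annotations`
#' (with `image_id`, `category_id` = lesion type, `bbox` as
#' `[x, y, w, h]`), `categories` — extended with the fields this pipeline
#' needs: per-image `eye_id`, `orientation_label` and `transform`
#' (scale, rotation_rad, tx, ty, field to panorama), per-eye `landmarks`
#' (disc, fovea, nasal ora radius, laterality) and `plus_present`.
#' Output is deterministic: identical inputs produce byte-identical
#' files.
#'
#' @param eye a `ground_truth_eye`.
#' @param detections detection/ground-truth data frame with columns
#'   `field_id`, `type`, `x0`, `y0`, `x1`, `y1` and optionally
#'   `confidence`.
#' @param path output JSON path.
#' @return `write_annotations` returns `path` invisibly;
#'   `read_annotations` returns a list with `images`, `detections` (in
#'   the package's column layout), `landmarks`, `transforms`,
#'   `plus_present`, `eye_id`.
#' @export
write_annotations <- function(eye, detections, path) {
  plan <- eye$plan
  tr <- attr(plan, "transforms")
  images <- lapply(seq_len(nrow(plan)), function(i) {
    t <- tr[[plan$field_id[i]]]
    list(id = i, file_name = paste0(eye$eye_id, "_", plan$field_id[i], ".png"),
         field_id = plan$field_id[i], width = plan$width[i],
         height = plan$height[i],
         orientation_label = plan$orientation_label[i],
         eye_id = eye$eye_id,
         transform = list(scale = t$scale, rotation_rad = t$rotation,
                          tx = t$tx, ty = t$ty))
  })
  anns <- lapply(seq_len(nrow(detections)), function(k) {
    d <- detections[k, ]
    out <- list(id = k, image_id = match(d$field_id, plan$field_id),
                category_id = as.integer(d$type),
                bbox = round(c(d$x0, d$y0, d$x1 - d$x0, d$y1 - d$y0), 6))
    if (!is.null(detections$confidence)) out$score <- round(d$confidence, 6)
    out
  })
  obj <- list(
    images = images,
    annotations = anns,
    categories = lapply(1:4, function(t) list(
      id = t, name = c("demarcation_line", "ridge",
                       "ridge_with_proliferation", "detachment")[t])),
    eye = list(eye_id = eye$eye_id, laterality = eye$laterality,
               plus_present = eye$plus_present,
               landmarks = list(disc_center = round(eye$disc_center, 6),
                                fovea_center = round(eye$fovea_center, 6),
                                ora_radius_nasal = eye$ora_radius_nasal)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  imgs <- obj$images
  fid_by_image <- vapply(imgs, function(i) i$field_id, "")
  names(fid_by_image) <- vapply(imgs, function(i) as.character(i$id), "")
  transforms <- stats::setNames(lapply(imgs, function(i)
    sim_transform(i$transform$scale, i$transform$rotation_rad,
                  i$transform$tx, i$transform$ty)), fid_by_image)
  dets <- if (length(obj$annotations)) do.call(rbind, lapply(obj$annotations, function(a) {
    b <- unlist(a$bbox)
    data.frame(field_id = fid_by_image[[as.character(a$image_id)]],
               type = a$category_id, x0 = b[1], y0 = b[2],
               x1 = b[1] + b[3], y1 = b[2] + b[4],
               confidence = if (is.null(a$score)) NA_real_ else a$score,
               stringsAsFactors = FALSE)
  })) else data.frame(field_id = character(), type = integer(), x0 = numeric(),
                      y0 = numeric(), x1 = numeric(), y1 = numeric(),
                      confidence = numeric(), stringsAsFactors = FALSE)
  lm <- obj$eye$landmarks
  list(eye_id = obj$eye$eye_id,
       laterality = obj$eye$laterality,
       plus_present = obj$eye$plus_present,
       landmarks = list(disc_center = unlist(lm$disc_center),
                        fovea_center = unlist(lm$fovea_center),
                        ora_radius_nasal = lm$ora_radius_nasal),
       transforms = transforms,
       images = data.frame(
         field_id = fid_by_image,
         orientation_label = vapply(imgs, function(i) i$orientation_label, ""),
         width = vapply(imgs, function(i) as.numeric(i$width), 0),
         height = vapply(imgs, function(i) as.numeric(i$height), 0),
         stringsAsFactors = FALSE, row.names = NULL),
       detections = dets)
}
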