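# Classical frequency-domain registration: log-polar cross-correlation of
# Fourier magnitudes for rotation/scale, then phase correlation for
# translation.  Deterministic and dependency-light; adequate for the
# glyph-rich synthetic rasters.  The montage interface also accepts
# externally supplied transforms, so a learned registration model can be
# plugged in unchanged.

hann2 <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = h))
  wx <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = w))
  outer(wy, wx)
}

fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

# Wrap a 0-based index into a signed offset.
wrap_index <- function(i, n) ifelse(i > n / 2, i - n, i)

# Subpixel refinement of a correlation peak by 1-D parabola fits.
subpixel_peak <- function(r, iy, ix) {
  h <- nrow(r); w <- ncol(r)
  at <- function(dy, dx) r[(iy - 1 + dy) %% h + 1, (ix - 1 + dx) %% w + 1]
  para <- function(m1, c0, p1) {
    den <- m1 - 2 * c0 + p1
    if (abs(den) < 1e-12) 0 else clamp(0.5 * (m1 - p1) / den, -0.5, 0.5)
  }
  c(dy = para(at(-1, 0), at(0, 0), at(1, 0)),
    dx = para(at(0, -1), at(0, 0), at(0, 1)))
}

# Translation t = (dx, dy) such that shifting `moving`'s content by +t
# aligns it with `fixed`; also returns the normalized peak height.
# `pad = TRUE` zero-pads to double size, turning the circular correlation
# into a linear one: shifts beyond half the frame are then unambiguous
# (no wrap-around alias), at the cost of a larger FFT.
phase_correlate <- function(fixed, moving, window = TRUE, pad = FALSE) {
  stopifnot(all(dim(fixed) == dim(moving)))
  fa <- fixed - mean(fixed); fb <- moving - mean(moving)
  if (window) { wdw <- hann2(nrow(fa), ncol(fa)); fa <- fa * wdw; fb <- fb * wdw }
  if (pad) {
    h <- nrow(fa); w <- ncol(fa)
    pa <- matrix(0, 2 * h, 2 * w); pb <- pa
    pa[1:h, 1:w] <- fa; pb[1:h, 1:w] <- fb
    fa <- pa; fb <- pb
  }
  A <- stats::fft(fa); B <- stats::fft(fb)
  R <- A * Conj(B)
  R <- R / (Mod(R) + 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  i <- arrayInd(which.max(r), dim(r))
  sp <- subpixel_peak(r, i[1], i[2])
  dy <- wrap_index(i[1] - 1, nrow(r)) + sp["dy"]
  dx <- wrap_index(i[2] - 1, ncol(r)) + sp["dx"]
  list(t = c(unname(dx), unname(dy)), peak = max(r))
}

# Log-polar resampling of an fft-shifted magnitude spectrum over the
# half-plane [0, pi) (magnitude spectra are 180-degree symmetric).
logpolar_spectrum <- function(img, n_theta = 720, n_r = 256, r_min = 4) {
  wdw <- hann2(nrow(img), ncol(img))
  m <- fftshift2(Mod(stats::fft((img - mean(img)) * wdw)))
  m <- log1p(m)
  h <- nrow(m); w <- ncol(m)
  cy <- floor(h / 2); cx <- floor(w / 2)    # 0-based centre after fftshift
  r_max <- min(h, w) / 2 - 1
  lr <- seq(log(r_min), log(r_max), length.out = n_r)
  th <- seq(0, pi, length.out = n_theta + 1)[-(n_theta + 1)]
  rr <- exp(lr)
  xs <- cx + outer(cos(th), rr)             # n_theta x n_r
  ys <- cy + outer(sin(th), rr)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 2 & y0 <= h - 2
  i00 <- x0 * h + y0 + 1
  v <- matrix(0, n_theta, n_r)
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * m[i00[ok]] +
    fx[ok] * (1 - fy[ok]) * m[i00[ok] + h] +
    (1 - fx[ok]) * fy[ok] * m[i00[ok] + 1] +
    fx[ok] * fy[ok] * m[i00[ok] + h + 1]
  list(lp = v, d_theta = pi / n_theta, d_logr = diff(lr[1:2]))
}

#' Estimate the similarity transform aligning two rasters
#'
#' Rotation and scale are recovered from the log-polar cross-correlation
#' of the two Fourier magnitude spectra; the moving raster is then
#' resampled at the recovered rotation/scale and the residual translation
#' found by phase correlation with subpixel peak interpolation.  The
#' returned transform maps moving-raster coordinates into fixed-raster
#' coordinates.  The alignment score is the Pearson correlation of the
#' overlapping pixels after warping, clamped to [0, 1].
#'
#' @param fixed,moving grayscale matrices of equal size with >= 25%
#'   overlap and non-constant intensity.
#' @param rotation_scale set `FALSE` to restrict the model to pure
#'   translation (skips the log-polar stage).
#' @param min_score score below which the result is flagged as an
#'   alignment failure.
#' @return List with `transform` (`sim_transform`), `score` in [0, 1],
#'   and `ok` (`score >= min_score`).
#' @export
estimate_pairwise <- function(fixed, moving, rotation_scale = TRUE,
                              min_score = 0.2) {
  stopifnot(all(dim(fixed) == dim(moving)))
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("constant-intensity raster cannot be registered")
  ctr <- c(ncol(fixed), nrow(fixed)) / 2
  bg <- mean(moving)

  # rotation/scale of `img` (already roughly translation-aligned to
  # fixed) from the log-polar cross-correlation of magnitude spectra
  rot_scale <- function(img) {
    la <- logpolar_spectrum(fixed)
    lb <- logpolar_spectrum(img)
    pc <- phase_correlate(la$lp, lb$lp, window = FALSE)
    theta <- pc$t[2] * la$d_theta           # row shift -> rotation
    scale <- exp(-pc$t[1] * la$d_logr)      # col shift -> log-scale
    if (theta > pi / 2) theta <- theta - pi
    if (theta <= -pi / 2) theta <- theta + pi
    scale <- clamp(scale, 0.5, 2)
    c(theta, scale)
  }

  # candidate base transforms; each is completed by a residual
  # translation, refined, and scored
  cands <- list(st_identity())
  if (rotation_scale) {
    rs <- rot_scale(moving)
    cands <- c(cands, list(st_about(rs[2], rs[1], ctr)))
    # magnitude spectra are only translation-invariant for circular
    # shifts: when the true translation is large, pre-align it by plain
    # phase correlation before the log-polar stage
    t0 <- phase_correlate(fixed, moving)$t
    pre <- sim_transform(1, 0, t0[1], t0[2])
    mov0 <- warp_raster(moving, pre, ncol(moving), nrow(moving), fill = bg)
    rs0 <- rot_scale(mov0)
    cands <- c(cands, list(st_compose(st_about(rs0[2], rs0[1], ctr), pre)))
  }

  complete <- function(base) {
    mov2 <- warp_raster(moving, base, ncol(moving), nrow(moving), fill = bg)
    pc2 <- phase_correlate(fixed, mov2, window = FALSE, pad = TRUE)
    tr <- st_compose(sim_transform(1, 0, pc2$t[1], pc2$t[2]), base)
    mov3 <- warp_raster(moving, tr, ncol(fixed), nrow(fixed), fill = NA)
    ok <- !is.na(mov3)
    if (sum(ok) > 100) {
      pc3 <- phase_correlate(ifelse(ok, fixed, mean(fixed)),
                             ifelse(ok, mov3, mean(fixed)),
                             window = FALSE, pad = TRUE)
      if (sqrt(sum(pc3$t^2)) < 5)
        tr <- st_compose(sim_transform(1, 0, pc3$t[1], pc3$t[2]), tr)
    }
    mov4 <- warp_raster(moving, tr, ncol(fixed), nrow(fixed), fill = NA)
    ok <- !is.na(mov4)
    score <- if (sum(ok) > 100 && stats::sd(fixed[ok]) > 0 && stats::sd(mov4[ok]) > 0)
      max(0, stats::cor(fixed[ok], mov4[ok])) else 0
    list(transform = tr, score = score)
  }

  best <- NULL
  for (base in cands) {
    got <- complete(base)
    if (is.null(best) || got$score > best$score) best <- got
  }
  # refinement: re-estimate rotation/scale on the aligned pair and fold
  # the correction into the transform
  refine <- function(cur, passes = 3) {
    for (pass in seq_len(passes)) {
      if (cur$score >= 0.995) break
      aligned <- warp_raster(moving, cur$transform, ncol(fixed), nrow(fixed),
                             fill = bg)
      rs2 <- rot_scale(aligned)
      ref <- complete(st_compose(st_about(rs2[2], rs2[1], ctr), cur$transform))
      if (ref$score <= cur$score) break
      cur <- ref
    }
    cur
  }
  if (rotation_scale) {
    best <- refine(best)
    # coarse rotation hypotheses as a fallback when the spectral
    # estimate collapsed (large translation and rotation together);
    # each hypothesis gets its own refinement before the comparison
    if (best$score < 0.9) {
      for (th in c(-12, -6, 6, 12) * pi / 180) {
        got <- refine(complete(st_about(1, th, ctr)), passes = 4)
        if (got$score > best$score) best <- got
      }
    }
  }
  best$ok <- best$score >= min_score
  best
}

#' Compose a panoramic montage from overlapping fields
#'
#' Pairwise transforms (estimated by [estimate_pairwise()] unless
#' supplied) are assembled into global field-to-panorama transforms by
#' chaining along the maximum-score spanning tree rooted at the anchor
#' field.  The anchor — by convention the disc-centred field — gets the
#' identity transform, so panorama coordinates inherit the disc-centred
#' frame.  The panorama raster is rendered by warping fields
#' last-writer-wins from the farthest tree node down to the anchor.
#'
#' @param rasters named list of grayscale field matrices.
#' @param anchor field id of the anchor (disc-centred) field.
#' @param pairwise optional precomputed pair list: each element a list
#'   with `fixed`, `moving` (field ids), `transform` (moving to fixed)
#'   and `score`; when `NULL` all unordered pairs are estimated.
#' @param min_score minimum score for a pair to enter the overlap graph.
#' @param rotation_scale passed to [estimate_pairwise()].
#' @return An object of class `montage`: `panorama`, `origin` (raster
#'   origin in panorama coordinates), `transforms` (global, per field),
#'   `residuals` (per non-tree overlapping pair, px), `scores`, `anchor`.
#' @export
compose_montage <- function(rasters, anchor = names(rasters)[1], pairwise = NULL,
                            min_score = 0.25, rotation_scale = TRUE) {
  ids <- names(rasters)
  stopifnot(length(ids) > 0, anchor %in% ids)
  if (length(ids) == 1) {
    mont <- structure(list(panorama = rasters[[1]], origin = c(0, 0),
                           transforms = stats::setNames(list(st_identity()), ids),
                           residuals = data.frame(), scores = data.frame(),
                           anchor = anchor), class = "montage")
    return(mont)
  }
  if (is.null(pairwise)) {
    pairwise <- list()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      est <- estimate_pairwise(rasters[[ids[i]]], rasters[[ids[j]]],
                               rotation_scale = rotation_scale,
                               min_score = min_score)
      pairwise[[length(pairwise) + 1]] <-
        list(fixed = ids[i], moving = ids[j], transform = est$transform,
             score = est$score)
    }
  }
  scores <- data.frame(fixed = vapply(pairwise, `[[`, "", "fixed"),
                       moving = vapply(pairwise, `[[`, "", "moving"),
                       score = vapply(pairwise, function(p) p$score, 0),
                       stringsAsFactors = FALSE)
  keep <- scores$score >= min_score
  g <- igraph::graph_from_data_frame(scores[keep, c("fixed", "moving")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  anchor_comp <- comp$membership[[anchor]]
  if (any(comp$membership != anchor_comp))
    stop("overlap graph disconnected; unreachable fields: ",
         paste(ids[comp$membership != anchor_comp], collapse = ", "))
  igraph::E(g)$weight <- 1 - scores$score[keep]
  igraph::E(g)$pair_index <- which(keep)
  tree <- igraph::mst(g)

  transforms <- stats::setNames(vector("list", length(ids)), ids)
  transforms[[anchor]] <- st_identity()
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  depth[anchor] <- 0
  queue <- anchor
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in names(igraph::neighbors(tree, cur))) {
      if (!is.na(depth[nb])) next
      eid <- igraph::get_edge_ids(tree, c(cur, nb))
      p <- pairwise[[igraph::E(tree)$pair_index[eid]]]
      t_nb_cur <- if (p$fixed == cur) p$transform else st_inverse(p$transform)
      transforms[[nb]] <- st_compose(transforms[[cur]], t_nb_cur)
      depth[nb] <- depth[cur] + 1
      queue <- c(queue, nb)
    }
  }

  # residuals: consistency of non-tree pairs with the global solution,
  # measured at the moving field's centre
  res <- list()
  for (k in seq_along(pairwise)) {
    p <- pairwise[[k]]
    if (p$score < min_score) next
    c_m <- c(ncol(rasters[[p$moving]]), nrow(rasters[[p$moving]])) / 2
    via_pair <- st_apply(st_compose(transforms[[p$fixed]], p$transform), c_m)
    via_global <- st_apply(transforms[[p$moving]], c_m)
    res[[length(res) + 1]] <- data.frame(
      fixed = p$fixed, moving = p$moving, score = p$score,
      residual_px = sqrt(sum((via_pair - via_global)^2)),
      stringsAsFactors = FALSE)
  }
  residuals <- if (length(res)) do.call(rbind, res) else data.frame()

  # panorama bounds over all warped field corners
  corners <- do.call(rbind, lapply(ids, function(f) {
    w <- ncol(rasters[[f]]); h <- nrow(rasters[[f]])
    st_apply(transforms[[f]], cbind(c(0, w, 0, w), c(0, 0, h, h)))
  }))
  origin <- floor(c(min(corners[, 1]), min(corners[, 2])))
  size <- ceiling(c(max(corners[, 1]), max(corners[, 2]))) - origin
  pano <- new_raster(size[1], size[2], NA_real_)
  for (f in ids[order(depth[ids], decreasing = TRUE)]) {
    t_shift <- st_compose(sim_transform(1, 0, -origin[1], -origin[2]),
                          transforms[[f]])
    layer <- warp_raster(rasters[[f]], t_shift, size[1], size[2], fill = NA)
    pano[!is.na(layer)] <- layer[!is.na(layer)]
  }
  pano[is.na(pano)] <- 0
  structure(list(panorama = pano, origin = origin, transforms = transforms,
                 residuals = residuals, scores = scores, anchor = anchor),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage: %d field(s), anchor %s, panorama %dx%d>\n",
              length(x$transforms), x$anchor,
              ncol(x$panorama), nrow(x$panorama)))
  invisible(x)
}

#' Re-project per-field detections into panorama coordinates
#'
#' Each detection box is mapped through its field's global transform
#' (axis-aligned hull of the mapped corners); the zoning anchor point is
#' the mapped box centre.  Duplicates arising from lesions seen in
#' several overlapping fields are merged when they have the same type and
#' centres closer than `merge_radius`, or when one box's centre lies
#' inside the other box (a copy clipped at a field border keeps its
#' centre inside the full box even when the centres drift apart): the
#' highest-confidence copy is kept, ties broken toward the larger
#' (unclipped) box and then the field whose centre is nearest the
#' lesion.  The merge is idempotent.
#'
#' @param detections data frame with `field_id`, `type`, `x0`, `y0`,
#'   `x1`, `y1` and optionally `confidence` (defaults to 1).
#' @param montage a `montage`, or a named list of field-to-panorama
#'   `sim_transform`s (e.g. generator ground truth).
#' @param merge_radius merge distance in panorama px (default a quarter
#'   disc diameter).
#' @param field_sizes optional named list of `c(width, height)` per
#'   field, used only for the nearest-field tie-break.
#' @return Lesion data frame: `lesion_id`, `type`, `x0`, `y0`, `x1`,
#'   `y1`, `confidence`, `field_id`, `n_merged`.
#' @export
map_lesions <- function(detections, montage, merge_radius = 15,
                        field_sizes = NULL) {
  transforms <- if (inherits(montage, "montage")) montage$transforms else montage
  empty <- data.frame(lesion_id = character(), type = integer(),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), confidence = numeric(),
                      field_id = character(), n_merged = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(detections) || nrow(detections) == 0) return(empty)
  unknown <- setdiff(unique(detections$field_id), names(transforms))
  if (length(unknown))
    stop("no transform for field(s): ", paste(unknown, collapse = ", "))
  conf <- if (is.null(detections$confidence)) rep(1, nrow(detections))
  else detections$confidence
  boxes <- t(vapply(seq_len(nrow(detections)), function(k)
    st_map_box(transforms[[detections$field_id[k]]],
               as.numeric(detections[k, c("x0", "y0", "x1", "y1")])),
    numeric(4)))
  mapped <- data.frame(type = as.integer(detections$type),
                       x0 = boxes[, 1], y0 = boxes[, 2],
                       x1 = boxes[, 3], y1 = boxes[, 4],
                       confidence = conf, field_id = detections$field_id,
                       stringsAsFactors = FALSE)

  # tie-break distance: lesion centre to source-field centre, in panorama
  cx <- (mapped$x0 + mapped$x1) / 2; cy <- (mapped$y0 + mapped$y1) / 2
  fdist <- vapply(seq_len(nrow(mapped)), function(k) {
    f <- mapped$field_id[k]
    fs <- if (!is.null(field_sizes)) field_sizes[[f]] else c(640, 480)
    fc <- st_apply(transforms[[f]], fs / 2)
    sqrt((cx[k] - fc[1])^2 + (cy[k] - fc[2])^2)
  }, numeric(1))
  area <- (mapped$x1 - mapped$x0) * (mapped$y1 - mapped$y0)
  is_dup <- function(k, others) {
    same <- mapped$type[others] == mapped$type[k]
    close <- (cx[others] - cx[k])^2 + (cy[others] - cy[k])^2 < merge_radius^2
    inside <- (cx[k] >= mapped$x0[others] & cx[k] < mapped$x1[others] &
                 cy[k] >= mapped$y0[others] & cy[k] < mapped$y1[others]) |
      (cx[others] >= mapped$x0[k] & cx[others] < mapped$x1[k] &
         cy[others] >= mapped$y0[k] & cy[others] < mapped$y1[k])
    same & (close | inside)
  }
  ord <- order(-mapped$confidence, -area, fdist)
  keep <- logical(nrow(mapped))
  for (k in ord) {
    kept <- which(keep)
    if (!any(is_dup(k, kept))) keep[k] <- TRUE
  }
  out <- mapped[keep, , drop = FALSE]
  n_merged <- vapply(which(keep), function(k)
    sum(is_dup(k, seq_len(nrow(mapped)))), integer(1))
  out$n_merged <- n_merged
  out <- out[order(out$x0, out$y0), , drop = FALSE]
  out$lesion_id <- sprintf("P%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("lesion_id", "type", "x0", "y0", "x1", "y1", "confidence",
          "field_id", "n_merged")]
}
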