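#' Similarity transforms between pixel coordinate frames
#'
#' A similarity transform maps a point \eqn{x} to \eqn{s R(\theta) x + t},
#' where \eqn{s > 0} is an isotropic scale, \eqn{R(\theta)} a rotation and
#' \eqn{t} a 2-D translation.  It is the motion model relating each fundus
#' field to the per-eye panorama: the contact camera is re-oriented between
#' shots but the retina is (locally) rigid, so scale + rotation +
#' translation captures the field-to-panorama mapping.
#'
#' All pixel coordinates in this package are 0-based, x rightward,
#' y downward (top-left origin); boxes are half-open
#' \eqn{[x_0, x_1) \times [y_0, y_1)}.
#'
#' @param scale positive scale factor.
#' @param rotation rotation angle in radians (positive = x towards y,
#'   i.e. clockwise on screen with y down).
#' @param tx,ty translation in pixels.
#' @return An object of class `sim_transform`.
#' @examples
#' t <- sim_transform(1, pi / 2, 10, 0)
#' st_apply(t, c(1, 0))  # (10, 1)
#' @export
sim_transform <- function(scale = 1, rotation = 0, tx = 0, ty = 0) {
  stopifnot(is.numeric(scale), length(scale) == 1, is.finite(scale), scale > 0,
            is.finite(rotation), is.finite(tx), is.finite(ty))
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 tx = as.numeric(tx), ty = as.numeric(ty)),
            class = "sim_transform")
}

#' @export
print.sim_transform <- function(x, ...) {
  cat(sprintf("<sim_transform scale=%.6g rotation=%.6g rad t=(%.6g, %.6g)>\n",
              x$scale, x$rotation, x$tx, x$ty))
  invisible(x)
}

#' @rdname sim_transform
#' @export
st_identity <- function() sim_transform(1, 0, 0, 0)

st_matrix <- function(t) {
  cs <- cos(t$rotation); sn <- sin(t$rotation)
  t$scale * matrix(c(cs, sn, -sn, cs), 2, 2)
}

#' Apply a similarity transform to points
#'
#' @param t a `sim_transform`.
#' @param pts a length-2 vector or an n x 2 matrix of (x, y) coordinates.
#' @return Transformed coordinates, same shape as `pts`.
#' @export
st_apply <- function(t, pts) {
  vec <- is.null(dim(pts))
  if (vec) pts <- matrix(pts, 1, 2)
  out <- pts %*% t(st_matrix(t))
  out[, 1] <- out[, 1] + t$tx
  out[, 2] <- out[, 2] + t$ty
  if (vec) drop(out) else out
}

#' Compose and invert similarity transforms
#'
#' `st_compose(a, b)` is the transform "apply `b`, then `a`"
#' (\eqn{a \circ b}); `st_inverse(t)` satisfies
#' `st_compose(t, st_inverse(t))` = identity.
#'
#' @param a,b,t `sim_transform` objects.
#' @return A `sim_transform`.
#' @export
st_compose <- function(a, b) {
  tb <- st_apply(a, c(b$tx, b$ty))
  sim_transform(a$scale * b$scale, a$rotation + b$rotation, tb[1], tb[2])
}

#' @rdname st_compose
#' @export
st_inverse <- function(t) {
  s <- 1 / t$scale; r <- -t$rotation
  cs <- cos(r); sn <- sin(r)
  tx <- -s * (cs * t$tx - sn * t$ty)
  ty <- -s * (sn * t$tx + cs * t$ty)
  sim_transform(s, r, tx, ty)
}

#' Map an axis-aligned box through a similarity transform
#'
#' The four corners are mapped and the axis-aligned hull of the images is
#' returned; under rotation the hull is the tightest axis-aligned cover of
#' the warped box.
#'
#' @param t a `sim_transform`.
#' @param box numeric vector `c(x0, y0, x1, y1)`, half-open.
#' @return `c(x0, y0, x1, y1)` of the mapped hull.
#' @export
st_map_box <- function(t, box) {
  stopifnot(length(box) == 4)
  corners <- cbind(box[c(1, 3, 1, 3)], box[c(2, 2, 4, 4)])
  m <- st_apply(t, corners)
  c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
}

st_params <- function(t) c(scale = t$scale, rotation = t$rotation,
                           tx = t$tx, ty = t$ty)

st_from_params <- function(p) sim_transform(p[[1]], p[[2]], p[[3]], p[[4]])

# Equivalent transform when rotation/scale act about a pivot c instead of
# the origin: x' = s R (x - c) + c + d.
st_about <- function(scale, rotation, pivot, d = c(0, 0)) {
  base <- sim_transform(scale, rotation, 0, 0)
  off <- pivot + d - st_apply(base, pivot)
  sim_transform(scale, rotation, off[1], off[2])
}
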