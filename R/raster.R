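# Grayscale rasters are plain numeric matrices in [0, 1], indexed
# [row = y + 1, col = x + 1] so that external coordinates stay 0-based with
# y downward.  RGB rasters are h x w x 3 arrays under the same convention.

new_raster <- function(width, height, value = 0) {
  matrix(value, nrow = height, ncol = width)
}

raster_size <- function(img) c(width = ncol(img), height = nrow(img))

#' Read and write rasters as PNG
#'
#' Grayscale matrices are written as 8-bit gray PNG, h x w x 3 arrays as
#' 8-bit RGB.  Values are clamped to [0, 1].
#'
#' @param img numeric matrix or h x w x 3 array in [0, 1].
#' @param path file path.
#' @return `read_raster` returns a grayscale matrix (RGB files are
#'   averaged); `write_raster` returns `path` invisibly.
#' @export
write_raster <- function(img, path) {
  img[img < 0] <- 0; img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , 1:3, drop = FALSE], c(1, 2), mean)
  x
}

#' Warp a raster through a similarity transform
#'
#' Produces an output raster of size `width` x `height` whose pixel at
#' (x, y) samples the source at `st_inverse(transform)` applied to (x, y);
#' `transform` therefore maps source coordinates to output coordinates.
#' Bilinear interpolation; samples falling outside the source get `fill`.
#'
#' @param src grayscale matrix.
#' @param transform `sim_transform` mapping source to output coordinates.
#' @param width,height output size in pixels.
#' @param fill background value for out-of-source samples.
#' @return A `height` x `width` matrix.
#' @export
warp_raster <- function(src, transform, width, height, fill = 0) {
  inv <- st_inverse(transform)
  xs <- rep(seq_len(width) - 1, each = height)
  ys <- rep(seq_len(height) - 1, times = width)
  p <- st_apply(inv, cbind(xs, ys))
  sx <- p[, 1]; sy <- p[, 2]
  h <- nrow(src); w <- ncol(src)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 2 & y0 <= h - 2
  out <- rep(fill, width * height)
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- (x0k) * h + y0k + 1          # column-major linear index
    v <- (1 - fxk) * (1 - fyk) * src[i00] +
      fxk * (1 - fyk) * src[i00 + h] +
      (1 - fxk) * fyk * src[i00 + 1] +
      fxk * fyk * src[i00 + h + 1]
    out[ok] <- v
  }
  matrix(out, nrow = height, ncol = width)
}

# --- drawing primitives (used by the synthetic renderer and overlays) ----

# Stamp value onto all pixels within `radius` of any of the given points.
# pts: n x 2 matrix of (x, y); vectorised over points x disk offsets.
stamp_points <- function(img, pts, radius, value) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 2)
  if (nrow(pts) == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  R <- ceiling(radius)
  off <- expand.grid(dx = -R:R, dy = -R:R)
  n <- nrow(pts); m <- nrow(off)
  px <- rep(pts[, 1], each = m); py <- rep(pts[, 2], each = m)
  cx <- round(px) + rep(off$dx, times = n)
  cy <- round(py) + rep(off$dy, times = n)
  keep <- (cx - px)^2 + (cy - py)^2 <= radius^2 &
    cx >= 0 & cx < w & cy >= 0 & cy < h
  if (!any(keep)) return(img)
  img[cx[keep] * h + cy[keep] + 1] <- value
  img
}

# Resample a polyline at roughly `step` px spacing (keeps vertices).
resample_polyline <- function(pts, step = 0.5) {
  if (nrow(pts) < 2) return(pts)
  segs <- lapply(seq_len(nrow(pts) - 1), function(i) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  })
  rbind(do.call(rbind, segs), pts[nrow(pts), , drop = FALSE])
}

# Draw a polyline with a given stroke width (pixel on iff its centre lies
# within width/2 of the sampled curve).
draw_polyline <- function(img, pts, width, value) {
  stamp_points(img, resample_polyline(pts, step = 0.75), width / 2, value)
}

draw_disk <- function(img, center, radius, value) {
  stamp_points(img, matrix(center, 1, 2), radius, value)
}

draw_circle <- function(img, center, radius, value, thickness = 1.5) {
  n <- max(64L, ceiling(2 * pi * radius))
  th <- seq(0, 2 * pi, length.out = n + 1)
  pts <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  stamp_points(img, pts, thickness / 2, value)
}

draw_box_outline <- function(img, box, value, thickness = 1.5) {
  p <- rbind(c(box[1], box[2]), c(box[3], box[2]), c(box[3], box[4]),
             c(box[1], box[4]), c(box[1], box[2]))
  stamp_points(img, resample_polyline(p, 0.5), thickness / 2, value)
}

# --- minimal 3x5 digit bitmaps for overlay labels (digits 0-4) ----------

.digit_bitmaps <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001")
)

draw_digit <- function(img, digit, origin, value, px = 2) {
  bm <- .digit_bitmaps[[as.character(digit)]]
  if (is.null(bm)) return(img)
  for (r in seq_along(bm)) {
    bits <- strsplit(bm[r], "")[[1]] == "1"
    for (c in which(bits)) {
      x0 <- origin[1] + (c - 1) * px; y0 <- origin[2] + (r - 1) * px
      xs <- x0:(x0 + px - 1); ys <- y0:(y0 + px - 1)
      xs <- xs[xs >= 0 & xs < ncol(img)]; ys <- ys[ys >= 0 & ys < nrow(img)]
      if (length(xs) && length(ys)) img[ys + 1, xs + 1] <- value
    }
  }
  img
}

gray_to_rgb <- function(img) {
  array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
}

# Apply a drawing function per channel of an RGB array.
rgb_draw <- function(rgb, fun, color, ...) {
  for (ch in 1:3) rgb[, , ch] <- fun(rgb[, , ch], ..., value = color[ch])
  rgb
}
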