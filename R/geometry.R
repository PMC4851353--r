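# Shared planar geometry helpers.
#
# Conventions used throughout the package:
#   * images are numeric matrices indexed [row, col] = [y + 1, x + 1] with
#     0-based pixel coordinates (x, y); origin top-left, x rightward,
#     y downward; a pixel's center sits at integer (x, y);
#   * angles follow the standard mathematical convention on (x, -y):
#     measured counter-clockwise, so the image-space direction vector of an
#     angle theta is (cos(theta), -sin(theta)).

#' Wrap angles to (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Unit direction vector of angle theta in image coordinates.
unit_vec <- function(theta) c(cos(theta), -sin(theta))

# Left-normal (theta rotated +90 degrees counter-clockwise in math coords),
# expressed in image coordinates.
normal_vec <- function(theta) c(-sin(theta), -cos(theta))

# Angle of an image-space displacement (dx, dy) in math convention.
vec_angle <- function(dx, dy) atan2(-dy, dx)

#' Corners of an oriented rectangle
#'
#' A rectangle is anchored at the midpoint of its front edge and spans
#' `length` pixels backwards along `-theta`; `width` is centered on the axis.
#'
#' @param anchor numeric length-2, front-edge midpoint (x, y) in pixels.
#' @param theta axis orientation in radians (pointing front-ward).
#' @param length,width rectangle dimensions in pixels.
#' @return A 4 x 2 matrix of corner coordinates (front-left, front-right,
#'   back-right, back-left).
#' @export
rect_corners <- function(anchor, theta, length, width) {
  u <- unit_vec(theta)
  n <- normal_vec(theta)
  hw <- width / 2
  rbind(
    anchor + hw * n,
    anchor - hw * n,
    anchor - length * u - hw * n,
    anchor - length * u + hw * n
  )
}

# Membership test of pixel centers (px, py) in an oriented rectangle.
# Half-open on the far side of each axis so that abutting rectangles do not
# double-claim a center and the rasterization is deterministic.
points_in_rect <- function(px, py, anchor, theta, length, width) {
  rx <- px - anchor[1]
  ry <- py - anchor[2]
  ct <- cos(theta)
  st <- sin(theta)
  s <- -(rx * ct - ry * st)        # depth behind the front edge
  t <- -(rx * st + ry * ct)        # signed lateral offset
  s >= 0 & s < length & t >= -width / 2 & t < width / 2
}

# Rasterize one oriented rectangle onto a logical canvas (in place value
# semantics: returns the modified canvas). Parts outside are clipped.
fill_rect <- function(canvas, anchor, theta, length, width) {
  co <- rect_corners(anchor, theta, length, width)
  h <- nrow(canvas)
  w <- ncol(canvas)
  x0 <- max(0L, as.integer(ceiling(min(co[, 1]))))
  x1 <- min(w - 1L, as.integer(floor(max(co[, 1]))))
  y0 <- max(0L, as.integer(ceiling(min(co[, 2]))))
  y1 <- min(h - 1L, as.integer(floor(max(co[, 2]))))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1
  ys <- y0:y1
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- points_in_rect(px, py, anchor, theta, length, width)
  if (any(inside)) {
    canvas[cbind(py[inside] + 1L, px[inside] + 1L)] <- TRUE
  }
  canvas
}

# Bilinear sampling of a grayscale image at fractional pixel coordinates
# (0-based). Coordinates are clamped to the border.
bilinear_sample <- function(img, xs, ys) {
  h <- nrow(img)
  w <- ncol(img)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- xs - x0; fy <- ys - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (i00 * (1 - fx) + i10 * fx) * (1 - fy) + (i01 * (1 - fx) + i11 * fx) * fy
}
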