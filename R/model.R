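# Chained-rectangle fish body model: pose construction, rendering and
# cover-ratio computation shared by the detection and tracking stages.

#' Rectangle chain specification
#'
#' Defines the fixed geometry of the body model: a chain of `n_r` oriented
#' rectangles from head to tail. The default sizes correspond to a fish of
#' about 260 px total length imaged from above: a 50 x 35 px head rectangle
#' followed by seven 30 px body segments of tapering width. The head
#' rectangle is deliberately longer than any body rectangle so that the nose
#' always falls inside it.
#'
#' @param n_r number of rectangles (>= 2).
#' @param lengths,widths numeric vectors of length `n_r`, in pixels.
#' @return An object of class `rect_spec`.
#' @examples
#' spec <- rect_spec()
#' sum(spec$lengths)  # overall model length, 260 px
#' @export
rect_spec <- function(n_r = 8L,
                      lengths = c(50, 30, 30, 30, 30, 30, 30, 30),
                      widths = c(35, 35, 35, 26, 20, 15, 11, 8)) {
  n_r <- as.integer(n_r)
  stopifnot(n_r >= 2L, length(lengths) == n_r, length(widths) == n_r,
            all(lengths > 0), all(widths > 0))
  if (any(lengths[1] <= lengths[-1])) {
    stop("the head rectangle must be the longest (lengths[1] > lengths[i])")
  }
  structure(list(n_r = n_r, lengths = as.numeric(lengths),
                 widths = as.numeric(widths)),
            class = "rect_spec")
}

#' @export
print.rect_spec <- function(x, ...) {
  cat("<rect_spec> ", x$n_r, " rectangles, total length ",
      sum(x$lengths), " px\n", sep = "")
  cat("  lengths:", paste(x$lengths, collapse = " "), "\n")
  cat("  widths: ", paste(x$widths, collapse = " "), "\n")
  invisible(x)
}

#' Scale a rectangle chain specification
#'
#' Optional per-detection hook for fish of a different apparent size; the
#' tracker itself always uses one fixed spec per run.
#'
#' @param spec a [rect_spec()].
#' @param factor positive scale factor applied to all lengths and widths.
#' @return A scaled `rect_spec`.
#' @export
scale_spec <- function(spec, factor) {
  stopifnot(inherits(spec, "rect_spec"), factor > 0)
  rect_spec(spec$n_r, spec$lengths * factor, spec$widths * factor)
}

#' Construct a fish pose from head joint and segment orientations
#'
#' Joints are chained backwards: rectangle `i` hinges at the back-edge
#' midpoint of rectangle `i - 1`, so `J_i = J_{i-1} - len_i * u(theta_i)`,
#' where `u` is the unit direction of `theta_i` (pointing from tail to head).
#'
#' @param J1 numeric length-2, the joint between head rectangle and first
#'   body rectangle (back-edge midpoint of the head rectangle), pixels.
#' @param theta numeric vector of `n_r` segment orientations in radians.
#' @param spec a [rect_spec()].
#' @param N optional nose point; defaults to `nose_margin` px behind the
#'   front edge of the head rectangle along its axis.
#' @param nose_margin distance (px) from the head-rectangle front edge back
#'   to the nominal nose point.
#' @param cover_ratio,frame,id optional metadata carried with the pose.
#' @return An object of class `fish_pose` with fields `G` (front-edge
#'   midpoint of the head rectangle), `N` (nose), `J` (joint matrix,
#'   `(n_r - 1) x 2`), `O` (back-edge midpoint of the last rectangle),
#'   `theta`, `cover_ratio`, `frame`, `id`.
#' @export
fish_pose <- function(J1, theta, spec, N = NULL, nose_margin = 20,
                      cover_ratio = NA_real_, frame = NA_integer_,
                      id = NA_integer_) {
  stopifnot(inherits(spec, "rect_spec"), length(theta) == spec$n_r)
  n_r <- spec$n_r
  u1 <- unit_vec(theta[1])
  G <- J1 + spec$lengths[1] * u1
  if (is.null(N)) N <- G - nose_margin * u1
  J <- matrix(0, nrow = n_r - 1L, ncol = 2L)
  J[1L, ] <- J1
  for (i in seq_len(n_r - 1L)[-1L]) {
    J[i, ] <- J[i - 1L, ] - spec$lengths[i] * unit_vec(theta[i])
  }
  O <- J[n_r - 1L, ] - spec$lengths[n_r] * unit_vec(theta[n_r])
  structure(list(G = G, N = N, J = J, O = O, theta = theta,
                 cover_ratio = cover_ratio, frame = frame, id = id),
            class = "fish_pose")
}

#' @export
print.fish_pose <- function(x, ...) {
  cat(sprintf("<fish_pose> frame %s, nose (%.1f, %.1f), heading %.1f deg, cover %.3f\n",
              as.character(x$frame), x$N[1], x$N[2],
              x$theta[1] * 180 / pi, x$cover_ratio))
  invisible(x)
}

# Front-edge anchor of rectangle i for a given pose: G for the head
# rectangle, J_{i-1} for body rectangles.
rect_anchor <- function(pose, i) {
  if (i == 1L) pose$G else pose$J[i - 1L, ]
}

#' Render a pose as a binary silhouette
#'
#' Rasterizes the union of the pose's oriented rectangles onto a logical
#' canvas. A pixel belongs to the silhouette when its center lies inside at
#' least one rectangle. Parts of the pose extending outside the canvas are
#' clipped silently.
#'
#' @param pose a [fish_pose()].
#' @param spec a [rect_spec()].
#' @param canvas_shape integer c(height, width) of the output raster.
#' @return A logical matrix of that shape (TRUE = fish pixel).
#' @export
render_pose <- function(pose, spec, canvas_shape) {
  stopifnot(inherits(pose, "fish_pose"), inherits(spec, "rect_spec"))
  canvas <- matrix(FALSE, nrow = canvas_shape[1], ncol = canvas_shape[2])
  for (i in seq_len(spec$n_r)) {
    canvas <- fill_rect(canvas, rect_anchor(pose, i), pose$theta[i],
                        spec$lengths[i], spec$widths[i])
  }
  canvas
}

# Logical membership of a set of pixel centers in the pose's rectangle
# union; px/py are 0-based coordinates.
pose_covers <- function(pose, spec, px, py) {
  covered <- rep(FALSE, length(px))
  for (i in seq_len(spec$n_r)) {
    idx <- which(!covered)
    if (!length(idx)) break
    inside <- points_in_rect(px[idx], py[idx], rect_anchor(pose, i),
                             pose$theta[i], spec$lengths[i], spec$widths[i])
    covered[idx[inside]] <- TRUE
  }
  covered
}

#' Cover ratio of a pose over a foreground region
#'
#' The fraction of the region's pixels that lie inside the union of the
#' pose's rectangles. Poses whose cover ratio falls below 0.8 are rejected
#' by both the detection and the tracking stage.
#'
#' @param pose a [fish_pose()].
#' @param spec a [rect_spec()].
#' @param region the foreground pixel set attributed to this fish: either a
#'   logical matrix (same shape as the frame) or a 2-column matrix of
#'   0-based (x, y) pixel coordinates.
#' @return A fraction in \[0, 1\].
#' @export
cover_ratio <- function(pose, spec, region) {
  xy <- region_coords(region)
  if (nrow(xy) == 0L) {
    stop("empty region: degenerate detection, cover ratio undefined")
  }
  mean(pose_covers(pose, spec, xy[, 1], xy[, 2]))
}

# Normalize a region argument to a 2-column matrix of 0-based (x, y).
region_coords <- function(region) {
  if (is.logical(region) && is.matrix(region)) {
    idx <- which(region, arr.ind = TRUE)
    cbind(idx[, 2] - 1L, idx[, 1] - 1L)
  } else if (is.matrix(region) && ncol(region) == 2L) {
    region
  } else {
    stop("region must be a logical matrix or a 2-column coordinate matrix")
  }
}

#' Convert poses to a tidy per-fish-per-frame table
#'
#' One row per pose in the flat CSV dialect used for all on-disk outputs:
#' `frame, id, N_x, N_y, G_x, G_y, J1_x .. J{n_r-1}_y, O_x, O_y,
#' theta_1 .. theta_{n_r}, cover_ratio`.
#'
#' @param poses a list of [fish_pose()] objects.
#' @param spec a [rect_spec()].
#' @return A tibble with one row per pose.
#' @export
poses_to_table <- function(poses, spec) {
  n_r <- spec$n_r
  jn <- as.vector(t(outer(seq_len(n_r - 1L), c("x", "y"),
                          function(i, a) paste0("J", i, "_", a))))
  cols <- c("frame", "id", "N_x", "N_y", "G_x", "G_y", jn,
            "O_x", "O_y", paste0("theta_", seq_len(n_r)), "cover_ratio")
  if (!length(poses)) {
    m <- matrix(numeric(0), ncol = length(cols), dimnames = list(NULL, cols))
    return(as_tibble(as.data.frame(m)))
  }
  rows <- lapply(poses, function(p) {
    c(p$frame, p$id, p$N, p$G, as.vector(t(p$J)), p$O, p$theta, p$cover_ratio)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  as_tibble(as.data.frame(m))
}

#' Rebuild pose objects from a pose table
#'
#' @param tab a tibble in the layout of [poses_to_table()].
#' @param spec a [rect_spec()].
#' @return A list of [fish_pose()] objects.
#' @export
table_to_poses <- function(tab, spec) {
  n_r <- spec$n_r
  lapply(seq_len(nrow(tab)), function(r) {
    row <- tab[r, ]
    J <- matrix(0, n_r - 1L, 2L)
    for (i in seq_len(n_r - 1L)) {
      J[i, ] <- c(row[[paste0("J", i, "_x")]], row[[paste0("J", i, "_y")]])
    }
    theta <- vapply(seq_len(n_r), function(i) row[[paste0("theta_", i)]], 0)
    structure(list(G = c(row$G_x, row$G_y), N = c(row$N_x, row$N_y),
                   J = J, O = c(row$O_x, row$O_y), theta = theta,
                   cover_ratio = row$cover_ratio,
                   frame = row$frame, id = row$id),
              class = "fish_pose")
  })
}
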