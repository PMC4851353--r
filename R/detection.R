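# Per-frame fish detection: background subtraction, boundary extraction,
# curvature-based nose detection, head placement and greedy rectangle-chain
# fitting.

#' Estimate a static background image
#'
#' Pixel-wise arithmetic mean of the supplied frames. With enough frames of
#' moving fish the mean converges to the empty plate.
#'
#' @param frames a list of grayscale matrices of identical dimensions.
#' @return A numeric matrix of the same dimensions.
#' @export
estimate_background <- function(frames) {
  n <- frames_length(frames)
  stopifnot(n >= 1L)
  acc <- frame_get(frames, 1L)
  d <- dim(acc)
  if (n > 1L) {
    for (i in 2:n) {
      f <- frame_get(frames, i)
      if (!identical(dim(f), d)) {
        stop("all frames must have identical dimensions")
      }
      acc <- acc + f
    }
  }
  acc / n
}

#' Segment foreground fish pixels
#'
#' Thresholds the absolute difference between a frame and the background.
#' The absolute difference makes the polarity configurable, although under
#' backlit imaging the fish are always darker than the plate.
#'
#' @param frame,background grayscale matrices of identical dimensions.
#' @param threshold gray-level difference above which a pixel is foreground.
#' @return A logical foreground mask.
#' @export
segment_foreground <- function(frame, background, threshold) {
  stopifnot(identical(dim(frame), dim(background)))
  abs(frame - background) > threshold
}

# Connected-component labeling (8-connectivity) with a minimum-area filter.
# Returns a list with the integer label matrix (small components zeroed) and
# a named vector of retained component areas.
label_components <- function(mask, min_area = 0) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labmat <- t(EBImage::imageData(lab))
  storage.mode(labmat) <- "integer"
  if (max(labmat) == 0L) {
    return(list(labels = labmat, areas = integer(0)))
  }
  nz <- which(labmat > 0L)
  lv <- labmat[nz]
  areas <- tabulate(lv)
  keep <- which(areas >= min_area)
  if (length(keep) < length(areas)) {
    # drop small components and relabel contiguously so that component k
    # matches the k-th traced contour downstream
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    lv <- relab[lv]
    labmat[nz] <- lv
    nz <- nz[lv > 0L]
    lv <- lv[lv > 0L]
  }
  # 0-based (x, y) pixel coordinates of each retained component, computed
  # once: downstream stages index into this instead of rescanning the
  # label matrix
  h <- nrow(labmat)
  xy <- cbind((nz - 1L) %/% h, (nz - 1L) %% h)
  coords <- split.data.frame(xy, lv)
  list(labels = labmat, areas = setNames(areas[keep], seq_along(keep)),
       coords = coords)
}

#' Extract equal-arc-length boundary curves
#'
#' Traces the closed outer boundary of every sufficiently large connected
#' component of a foreground mask and resamples it to (approximately) equal
#' arc-length spacing. Curves are oriented counter-clockwise in the
#' mathematical (x, -y) convention, so a convex silhouette has positive
#' curvature everywhere.
#'
#' @param mask logical foreground mask.
#' @param spacing target arc-length distance between adjacent points, px.
#' @param min_area components smaller than this (px) are dropped.
#' @param labeled optional precomputed [label_components] result for the
#'   same mask, to avoid relabeling.
#' @return A list of `boundary_curve` objects, each with fields `B`
#'   (n x 2 matrix of 0-based (x, y) points), `spacing` (realized spacing)
#'   and `label` (the component id in the label matrix).
#' @export
extract_boundary <- function(mask, spacing = 1, min_area = 0,
                             labeled = NULL) {
  lc <- if (is.null(labeled)) label_components(mask, min_area) else labeled
  labmat <- lc$labels
  if (!length(lc$areas)) return(list())
  oc <- EBImage::ocontour(EBImage::Image(t(labmat)))
  keep <- as.integer(names(lc$areas))
  curves <- list()
  for (k in keep) {
    pts <- oc[[k]]
    if (is.null(pts) || nrow(pts) < 4L) next
    cur <- resample_closed(pts, spacing)
    if (nrow(cur$B) < 8L) next
    cur$label <- k
    curves[[length(curves) + 1L]] <- structure(cur, class = "boundary_curve")
  }
  curves
}

# Resample a closed polyline (n x 2, (x, y)) to equal arc-length spacing and
# enforce counter-clockwise winding in the (x, -y) math convention.
resample_closed <- function(pts, spacing) {
  # signed area in math coords; reverse if clockwise
  x <- pts[, 1]; y <- -pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  if (sum(x * y2 - x2 * y) / 2 < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n <- max(4L, round(total / spacing))
  at <- (seq_len(n) - 1L) * total / n
  xs <- stats::approx(cum, closed[, 1], xout = at)$y
  ys <- stats::approx(cum, closed[, 2], xout = at)$y
  list(B = cbind(xs, ys), spacing = total / n)
}

#' Discrete curvature profile of a boundary curve
#'
#' The tangential angle at each point is estimated from its immediate cyclic
#' neighbors with the four-quadrant arctangent; the curvature is the wrapped
#' difference of tangential angles at the two neighbors `neighbor_arc` px
#' ahead of and behind the point, divided by the arc length between them.
#' Curvature is positive where the curve bends left (convex for a
#' counter-clockwise wound curve).
#'
#' @param curve a `boundary_curve` from [extract_boundary()].
#' @param neighbor_arc arc-length offset of the tangent sample points, px.
#' @return A `curvature_profile`: list with `C` (signed curvature per point,
#'   rad/px), `phi` (tangential angle per point), `neighbor_arc`, `spacing`.
#' @export
compute_curvature <- function(curve, neighbor_arc = 8) {
  B <- curve$B
  n <- nrow(B)
  l <- max(1L, round(neighbor_arc / curve$spacing))
  if (n <= 2L * l + 2L) stop("boundary curve too short for curvature estimation")
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  phi <- atan2(-(B[nxt, 2] - B[prv, 2]), B[nxt, 1] - B[prv, 1])
  # cumulative unwrapping of the tangential angle: differences across the
  # curvature window are then free of the +/- pi ambiguity that a pairwise
  # wrap would suffer at sharp tail tips, and the discrete total-turning
  # identity sum(C * ds) = 2 pi holds exactly for simple curves
  phi_u <- cumsum(c(phi[1], wrap_angle(diff(phi))))
  winding <- phi_u[n] - phi_u[1] + wrap_angle(phi[1] - phi[n])
  idx <- seq_len(n)
  fwd_i <- idx + l
  bwd_i <- idx - l
  phi_fwd <- phi_bwd <- numeric(n)
  fw <- fwd_i > n
  phi_fwd[!fw] <- phi_u[fwd_i[!fw]]
  phi_fwd[fw] <- phi_u[fwd_i[fw] - n] + winding
  bw <- bwd_i < 1L
  phi_bwd[!bw] <- phi_u[bwd_i[!bw]]
  phi_bwd[bw] <- phi_u[bwd_i[bw] + n] - winding
  C <- (phi_fwd - phi_bwd) / (2 * l * curve$spacing)
  structure(list(C = C, phi = phi, neighbor_arc = l * curve$spacing,
                 spacing = curve$spacing, n = n),
            class = "curvature_profile")
}

#' Locate nose (and tail) candidates on a curvature profile
#'
#' Finds local curvature maxima above `kappa_min` with cyclic non-maximum
#' suppression. A blob yielding exactly two maxima is treated as an isolated
#' fish: the lower peak is the nose (the snout is blunter than the tail
#' tip), the higher one the tail. Blobs with any other number of peaks are
#' treated as potentially occluding fish and every supra-threshold maximum
#' is returned as a nose candidate to be validated downstream by body
#' fitting. Negative-curvature intersection corners are never candidates.
#'
#' @param profile a `curvature_profile`.
#' @param kappa_min curvature threshold in rad/px.
#' @param nms_window arc-length window (px) for non-maximum suppression.
#' @param curve optional `boundary_curve` the profile was computed from;
#'   when supplied, candidates must pass a tip test: the boundary
#'   `tip_arc` px to either side must recede at least `tip_depth` px
#'   behind the candidate along its outward direction, which keeps shallow
#'   convex corners of a strongly bent body from masquerading as tips.
#' @param tip_arc,tip_depth tip-test support arc and required recession, px.
#' @return A list of candidates, each `list(nose = index, tail = index or
#'   NA)`; empty if no supra-threshold maximum exists.
#' @export
find_nose_tail <- function(profile, kappa_min = 0.08, nms_window = 40,
                           curve = NULL, tip_arc = 20, tip_depth = 10) {
  C <- profile$C
  n <- profile$n
  win <- max(1L, round(nms_window / profile$spacing))
  ord <- order(C, decreasing = TRUE)
  peaks <- integer(0)
  for (i in ord) {
    if (C[i] <= kappa_min) break
    if (!length(peaks)) {
      peaks <- i
    } else {
      d <- abs(peaks - i)
      d <- pmin(d, n - d)
      if (all(d > win)) peaks <- c(peaks, i)
    }
  }
  if (!length(peaks)) return(list())
  peaks <- vapply(peaks, refine_peak, numeric(1),
                  C = C, kappa_min = kappa_min, win = win)
  if (!is.null(curve)) {
    keep <- vapply(peaks, function(p) {
      is_tip(curve, p, tip_arc / profile$spacing, tip_depth)
    }, logical(1))
    peaks <- peaks[keep]
    if (!length(peaks)) return(list())
  }
  if (length(peaks) == 2L) {
    # peaks is sorted by decreasing curvature: peaks[2] is the lower peak
    return(list(list(nose = peaks[2L], tail = peaks[1L])))
  }
  lapply(peaks, function(p) list(nose = p, tail = NA_integer_))
}

# Refine a curvature peak to the centroid of its supra-threshold run:
# rasterization noise makes the raw argmax wander across a blunt maximum,
# while the excess-curvature centroid stays put on the anatomical tip.
# Returns a fractional (1-based, cyclic) boundary index.
refine_peak <- function(peak, C, kappa_min, win) {
  n <- length(C)
  offs <- (-win):win
  idx <- ((peak - 1L + offs) %% n) + 1L
  wts <- pmax(C[idx] - kappa_min, 0)
  # restrict to the contiguous supra-threshold run containing the peak
  below <- which(wts == 0)
  pos <- win + 1L
  lo <- max(c(0L, below[below < pos]))
  hi <- min(c(length(offs) + 1L, below[below > pos]))
  sel <- (lo + 1L):(hi - 1L)
  shift <- sum(offs[sel] * wts[sel]) / sum(wts[sel])
  ((peak - 1 + shift) %% n) + 1
}

# Tip test: at a body extremity (nose or tail) the boundary a little way
# along both sides recedes far behind the point in its outward direction;
# at a shallow convex corner it stays nearly level with it.
is_tip <- function(curve, idx, l_pts, depth) {
  B <- curve$B
  P <- boundary_at(B, idx)
  A <- boundary_at(B, idx - l_pts)
  Bp <- boundary_at(B, idx + l_pts)
  out <- P - (A + Bp) / 2
  nrm <- sqrt(sum(out^2))
  if (nrm == 0) return(FALSE)
  out <- out / nrm
  pa <- sum((A - P) * out)
  pb <- sum((Bp - P) * out)
  pa < -depth && pb < -depth
}

# Boundary point at a fractional cyclic index (linear interpolation).
boundary_at <- function(B, idx) {
  n <- nrow(B)
  i0 <- floor(idx)
  f <- idx - i0
  a <- ((i0 - 1) %% n) + 1L
  b <- (i0 %% n) + 1L
  B[a, ] * (1 - f) + B[b, ] * f
}

#' Head observation from a detected nose point
#'
#' The head orientation is the direction of the perpendicular bisector of
#' the segment joining the two boundary neighbors `neighbor_arc` px either
#' side of the nose, signed to point outward through the nose. The head
#' rectangle is placed with its front edge `nose_margin` px ahead of the
#' nose along that direction, which puts the nose strictly inside it, and a
#' grayscale patch of the head rectangle rotated to horizontal is sampled
#' from the frame.
#'
#' @param curve a `boundary_curve`.
#' @param nose_index index of the nose point on the curve.
#' @param spec a [rect_spec()].
#' @param frame grayscale image the patch is sampled from.
#' @param neighbor_arc arc offset (px) of the bisector support points.
#' @param nose_margin distance (px) from the nose to the head-rectangle
#'   front edge.
#' @return A `head_observation`: list with `N`, `theta1`, `J1`, `G`,
#'   `patch` (a `widths[1] x lengths[1]` matrix).
#' @export
head_from_nose <- function(curve, nose_index, spec, frame,
                           neighbor_arc = 8, nose_margin = 10) {
  B <- curve$B
  n <- nrow(B)
  l <- neighbor_arc / curve$spacing
  # average a few boundary points around each support point to damp
  # rasterization noise in the bisector direction; fractional nose indices
  # (from sub-sample peak refinement) are interpolated
  navg <- function(center) {
    pts <- vapply(-3:3, function(k) boundary_at(B, center + k), numeric(2))
    rowMeans(pts)
  }
  N <- boundary_at(B, nose_index)
  # the bisector direction from a single support arc carries a degree or
  # two of rasterization tilt; averaging the bisector over a small family
  # of support arcs around `neighbor_arc` damps it
  angs <- vapply(l * c(0.75, 1, 1.25, 1.5), function(lk) {
    M <- (navg(nose_index - lk) + navg(nose_index + lk)) / 2
    d <- N - M
    if (all(d == 0)) d <- c(1, 0)
    vec_angle(d[1], d[2])
  }, 0)
  theta1 <- atan2(mean(sin(angs)), mean(cos(angs)))
  u <- unit_vec(theta1)
  G <- N + nose_margin * u
  J1 <- G - spec$lengths[1] * u
  patch <- sample_head_patch(frame, G, theta1, spec$lengths[1], spec$widths[1])
  structure(list(N = N, theta1 = theta1, J1 = J1, G = G, patch = patch),
            class = "head_observation")
}

# Sample the head-rectangle image patch rotated to horizontal: rows run
# across the head (width), columns from front edge to back edge (length).
sample_head_patch <- function(frame, G, theta1, len, wid) {
  u <- unit_vec(theta1)
  nv <- normal_vec(theta1)
  w <- as.integer(round(len))
  h <- as.integer(round(wid))
  s <- (seq_len(w) - 0.5)               # depth behind front edge
  t <- (seq_len(h) - 0.5) - wid / 2     # lateral offset
  S <- rep(s, each = h)
  Tt <- rep(t, times = w)
  xs <- G[1] - S * u[1] + Tt * nv[1]
  ys <- G[2] - S * u[2] + Tt * nv[2]
  matrix(bilinear_sample(frame, xs, ys), nrow = h, ncol = w)
}

# Greedy sequential chain fitting shared by detection and tracking.
#
# For each body rectangle i = 2..n_r, n_pb candidate angles are drawn from
# `angle_fun(i)`; the candidate whose rectangle covers the largest number of
# still-uncovered region pixels is kept (ties broken by smallest wrapped
# angular distance to the previous segment). The final cover ratio counts
# region pixels inside the union of all n_r rectangles.
fit_chain <- function(J1, theta1, spec, region_xy, n_pb, angle_fun,
                      cover_min = 0.8, nose_margin = 10) {
  n_r <- spec$n_r
  theta <- numeric(n_r)
  theta[1] <- theta1
  m <- nrow(region_xy)
  if (m == 0L) {
    pose <- fish_pose(J1, rep(theta1, n_r), spec, nose_margin = nose_margin,
                      cover_ratio = 0)
    attr(pose, "valid") <- FALSE
    return(pose)
  }
  px <- region_xy[, 1]
  py <- region_xy[, 2]
  covered <- points_in_rect(px, py, J1 + spec$lengths[1] * unit_vec(theta1),
                            theta1, spec$lengths[1], spec$widths[1])
  Jprev <- J1
  for (i in 2:n_r) {
    len <- spec$lengths[i]
    wid <- spec$widths[i]
    cand <- angle_fun(i)
    # coarse radius prefilter around the hinge point
    rx <- px - Jprev[1]
    ry <- py - Jprev[2]
    reach2 <- (sqrt(len^2 + (wid / 2)^2) + 1.5)^2
    near <- which(!covered & (rx * rx + ry * ry) <= reach2)
    if (length(near)) {
      ct <- cos(cand); st <- sin(cand)
      M <- cbind(rx[near], ry[near])
      S <- M %*% rbind(-ct, st)
      Tt <- M %*% rbind(-st, -ct)
      inside <- S >= 0 & S < len & Tt >= -wid / 2 & Tt < wid / 2
      counts <- colSums(inside)
    } else {
      counts <- rep(0L, length(cand))
    }
    # near-ties (within 0.5% of the best count) are broken towards the
    # smallest angular change from the previous segment: many candidate
    # angles cover almost the same pixel count on a wide region, and the
    # fish body bends smoothly
    best <- which(counts >= max(counts) - max(1, 0.005 * max(counts)))
    if (length(best) > 1L) {
      best <- best[which.min(abs(wrap_angle(cand[best] - theta[i - 1L])))]
    }
    theta[i] <- cand[best]
    if (length(near)) covered[near[inside[, best]]] <- TRUE
    Jprev <- Jprev - len * unit_vec(theta[i])
  }
  pose <- fish_pose(J1, theta, spec, nose_margin = nose_margin,
                    cover_ratio = mean(covered))
  attr(pose, "valid") <- pose$cover_ratio >= cover_min
  pose
}

#' Fit the body rectangle chain of a newly detected fish
#'
#' Starting from the head joint `J1` and head orientation `theta1`, each
#' body rectangle is fitted in turn by drawing `n_pb` candidate angles
#' uniformly on \[0, 2 pi) and keeping the one covering the most foreground
#' pixels not yet claimed by earlier rectangles. The pose is flagged invalid
#' when the final cover ratio is below `cover_min`.
#'
#' @param J1 head joint (back-edge midpoint of the head rectangle).
#' @param theta1 head orientation, radians.
#' @param spec a [rect_spec()].
#' @param region foreground region for this fish (logical matrix or
#'   2-column 0-based coordinate matrix).
#' @param n_pb number of candidate angles per rectangle.
#' @param cover_min minimum admissible cover ratio.
#' @param nose_margin nose-to-front-edge margin, px.
#' @return A [fish_pose()] with attribute `valid`.
#' @export
fit_chain_detection <- function(J1, theta1, spec, region, n_pb = 256,
                                cover_min = 0.8, nose_margin = 10) {
  region_xy <- region_coords(region)
  fit_chain(J1, theta1, spec, region_xy, n_pb,
            angle_fun = function(i) runif(n_pb, 0, 2 * pi),
            cover_min = cover_min, nose_margin = nose_margin)
}

#' Detect all fish in one frame
#'
#' Composes background subtraction, component labeling, boundary
#' extraction, curvature-based nose detection, head placement and chain
#' fitting over every blob. Poses with a cover ratio below
#' `params$cover_min` are removed from the result.
#'
#' @param frame grayscale matrix.
#' @param background background matrix of the same shape.
#' @param params a parameter list from [fishchain_config()].
#' @param labeled optional precomputed `list(mask, labels)` to avoid
#'   recomputing the segmentation.
#' @return A list of detections, each
#'   `list(pose, head (head_observation), label)`; the head fields carry
#'   the measured nose, orientation, `J1` and patch used by the tracker.
#' @export
detect_frame <- function(frame, background, params = fishchain_config(),
                         labeled = NULL) {
  if (is.null(labeled)) {
    mask <- segment_foreground(frame, background, params$threshold)
    lc <- label_components(mask, params$min_area)
  } else {
    lc <- labeled
  }
  labmat <- lc$labels
  curves <- extract_boundary(labmat > 0L, spacing = params$spacing,
                             min_area = params$min_area, labeled = lc)
  detections <- list()
  for (cur in curves) {
    prof <- compute_curvature(cur, params$neighbor_arc)
    cands <- find_nose_tail(prof, params$kappa_min, params$nms_window,
                            curve = cur)
    if (!length(cands)) next
    region_xy <- if (!is.null(lc$coords)) lc$coords[[as.character(cur$label)]]
                 else component_coords(labmat, cur$label)
    for (cand in cands) {
      head <- head_from_nose(cur, cand$nose, params$spec, frame,
                             params$neighbor_arc, params$nose_margin)
      pose <- fit_chain_detection(head$J1, head$theta1, params$spec,
                                  region_xy, params$n_pb,
                                  params$cover_min, params$nose_margin)
      if (!isTRUE(attr(pose, "valid"))) next
      pose$N <- head$N
      pose$frame <- NA_integer_
      detections[[length(detections) + 1L]] <-
        list(pose = pose, head = head, label = cur$label)
    }
  }
  detections
}

# 0-based (x, y) coordinates of the pixels of one labeled component.
component_coords <- function(labmat, label) {
  idx <- which(labmat == label, arr.ind = TRUE)
  cbind(idx[, 2] - 1L, idx[, 1] - 1L)
}
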