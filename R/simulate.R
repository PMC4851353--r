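# Seeded synthetic generator of top-view image sequences of articulated
# fish with exported ground truth, emulating backlit shallow-water imaging:
# bright uniform plate, dark texture-poor silhouettes, smooth trajectories
# with per-frame displacements of a few pixels, sinusoidal body undulation
# with a backward-travelling phase lag, and optional scripted crossings.
#
# Each fish is a chained-rectangle body whose joints follow the path
# history of its head joint (like carriages following an engine), plus a
# sinusoidal angular undulation. The head silhouette is a rectangle base
# capped by a parabolically tapering snout whose apex is the ground-truth
# nose: the taper gives the boundary a single positive-curvature maximum at
# the nose that is lower than the tail-tip peak, as in real fish.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions: a handful of ~240 px
#' fish in a 1024 px square arena at 100 fps-equivalent motion (a few px
#' per frame), plate gray 200 vs fish gray 40 with sigma = 4 sensor noise.
#'
#' @param n_fish number of fish (1-20).
#' @param arena c(height, width) of the arena in pixels.
#' @param n_frames number of frames.
#' @param seed integer seed; the whole sequence is a deterministic function
#'   of the configuration.
#' @param spec body-model [rect_spec()].
#' @param plate,fish_gray plate and fish intensities (0-255, plate > fish).
#' @param noise_sd Gaussian pixel-noise standard deviation, gray levels.
#' @param speed c(min, max) cruising speed, px/frame.
#' @param undulation_amp tail-beat angular amplitude, radians.
#' @param undulation_period tail-beat period, frames.
#' @param phase_lag per-segment phase lag of the undulation wave, radians
#'   (positive lag = backward-travelling propulsive wave).
#' @param turn_sd,turn_max random heading-change sd and bound, rad/frame.
#' @param wall_margin distance from a wall at which fish steer away, px.
#' @param sep_radius distance within which fish steer away from another
#'   fish's body, px.
#' @param crossings optional scripted crossing events: a data frame with
#'   columns `frame` (approximate crossing frame) and `id1`, `id2` (the
#'   fish pair steered through a brief overlap).
#' @param stripe_amp amplitude (gray levels) of the per-fish pigment
#'   stripes. Real zebrafish carry individual pigmentation; the stripes
#'   (fish-specific wavelength and phase, anchored to the rigid head) give
#'   each fish a stable appearance fingerprint, without which the
#'   normalized-cross-correlation term of the association cost carries no
#'   information on texture-free silhouettes. Set to 0 for uniform fish.
#' @param nose_len length of the head (base + snout cap) ahead of `J1`, px.
#' @param cap_len length of the parabolic snout cap, px.
#' @param spawn optional `n_fish x 3` matrix of initial `(x, y, heading)`;
#'   by default fish spawn on a jittered grid with random headings.
#'   Prescribed spawns are useful for staged scenarios (e.g. placing
#'   crossing pairs in separate regions of the arena).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_fish = 5L, arena = c(1400L, 1400L), n_frames = 200L,
                       seed = 1L, spec = rect_spec(),
                       plate = 200, fish_gray = 40, noise_sd = 4,
                       speed = c(2.5, 5), undulation_amp = 0.25,
                       undulation_period = 20, phase_lag = 0.8,
                       turn_sd = 0.03, turn_max = 0.06,
                       wall_margin = 140, sep_radius = 250,
                       crossings = NULL, stripe_amp = 30,
                       nose_len = 40, cap_len = 18, spawn = NULL) {
  stopifnot(n_fish >= 1L, plate > fish_gray, plate <= 255, fish_gray >= 0,
            all(speed > 0), speed[2] <= 10)
  body_len <- sum(spec$lengths[-1]) + nose_len
  if (min(arena) < body_len + 2 * wall_margin) {
    stop("arena too small for the fish body length")
  }
  structure(list(n_fish = as.integer(n_fish), arena = as.integer(arena),
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 spec = spec, plate = plate, fish_gray = fish_gray,
                 noise_sd = noise_sd, speed = speed,
                 undulation_amp = undulation_amp,
                 undulation_period = undulation_period,
                 phase_lag = phase_lag, turn_sd = turn_sd,
                 turn_max = turn_max, wall_margin = wall_margin,
                 sep_radius = sep_radius, crossings = crossings,
                 stripe_amp = stripe_amp,
                 nose_len = nose_len, cap_len = cap_len, spawn = spawn),
            class = "sim_config")
}

# --- path machinery --------------------------------------------------------

# A fish's body is laid out along the recent path of its head joint. The
# path is a polyline of J1 positions, newest last; `arc` holds cumulative
# arc length from the oldest point.
path_new <- function(J1, heading, back = 400) {
  u <- unit_vec(heading)
  k <- 40L
  s <- seq(back, 0, length.out = k)
  pts <- cbind(J1[1] - s * u[1], J1[2] - s * u[2])
  list(pts = pts, arc = c(0, cumsum(sqrt(rowSums(diff(pts)^2)))))
}

path_push <- function(path, J1) {
  last <- path$pts[nrow(path$pts), ]
  d <- sqrt(sum((J1 - last)^2))
  path$pts <- rbind(path$pts, J1)
  path$arc <- c(path$arc, path$arc[length(path$arc)] + d)
  if (nrow(path$pts) > 400L) {
    path$pts <- path$pts[-1, , drop = FALSE]
    path$arc <- path$arc[-1]
  }
  path
}

# Position at arc length `a` behind the head (a = 0 is the head itself).
path_point <- function(path, a) {
  total <- path$arc[length(path$arc)]
  at <- max(path$arc[1], total - a)
  x <- stats::approx(path$arc, path$pts[, 1], xout = at)$y
  y <- stats::approx(path$arc, path$pts[, 2], xout = at)$y
  c(x, y)
}

# Forward tangent direction (radians, math convention) at arc length a.
path_dir <- function(path, a, delta = 3) {
  p_ahead <- path_point(path, max(0, a - delta))
  p_behind <- path_point(path, a + delta)
  d <- p_ahead - p_behind
  if (all(d == 0)) d <- c(1, 0)
  vec_angle(d[1], d[2])
}

# Ground-truth pose of one fish at time t from its path, with sinusoidal
# undulation added segment-wise (chain lengths stay exact by construction).
# `und_scale` in [0, 1] attenuates the undulation: scripted fish glide
# (burst-and-glide style) through a staged crossing so the contact
# geometry is not jittered by the tail beat.
sim_pose <- function(path, t, cfg, phase0, und_scale = 1) {
  spec <- cfg$spec
  n_r <- spec$n_r
  theta <- numeric(n_r)
  theta[1] <- path_dir(path, spec$lengths[1] / 2)
  J <- matrix(0, n_r - 1L, 2L)
  J[1, ] <- path$pts[nrow(path$pts), ]
  wobble <- 2 * pi * t / cfg$undulation_period + phase0
  amp <- cfg$undulation_amp * und_scale
  arc_off <- 0
  for (i in 2:n_r) {
    mid <- arc_off + spec$lengths[i] / 2
    raw <- path_dir(path, mid)
    theta[i] <- raw + amp * sin(wobble - cfg$phase_lag * (i - 1))
    if (i < n_r) J[i, ] <- J[i - 1L, ] - spec$lengths[i] * unit_vec(theta[i])
    arc_off <- arc_off + spec$lengths[i]
  }
  J1 <- J[1, ]
  u1 <- unit_vec(theta[1])
  O <- J[n_r - 1L, ] - spec$lengths[n_r] * unit_vec(theta[n_r])
  list(J = J, theta = theta, N = J1 + cfg$nose_len * u1,
       G = J1 + spec$lengths[1] * u1, O = O)
}

# Outline polygon of one fish's silhouette. The body is a smoothly
# tapering ribbon around the joint chain: cross-sections at the joints use
# mitered normals (bisector of adjacent segment directions) and the width
# of the *following* rectangle, so the stepped rectangle model always
# covers the silhouette laterally and the sides show no spurious convex
# corners. The snout is a cone of constant side slope 0.5 with a 2 px
# rounded tip at the ground-truth nose, blending near-flat into the head:
# its in-window curvature (~0.138 rad/px over a symmetric plateau) is the
# only convex structure of the head, so the excess-curvature centroid
# localizes the nose on the apex. The tail tapers at slope 0.18 to a point
# (~0.174 rad/px), keeping the tail peak reliably above the nose peak.
sim_fish_outline <- function(pose, cfg) {
  spec <- cfg$spec
  n_r <- spec$n_r
  th <- pose$theta
  J1 <- pose$J[1, ]
  u1 <- unit_vec(th[1])
  hw1 <- spec$widths[1] / 2
  # snout profile knots (arc distance from apex as fraction of nose_len,
  # half-width as fraction of the head half-width): rounded 2 px micro-tip,
  # constant-slope cone past the curvature window, near-flat blend
  r_frac <- c(0.05, 0.7, 1)
  w_frac <- c(0.126, 0.869, 1)
  secs <- list(list(p = pose$N, dir = th[1], hw = 0))
  for (kk in seq_along(r_frac)) {
    secs[[length(secs) + 1L]] <- list(
      p = J1 + (1 - r_frac[kk]) * cfg$nose_len * u1,
      dir = th[1], hw = w_frac[kk] * hw1)
  }
  bis <- function(a, b) {
    v <- unit_vec(a) + unit_vec(b)
    vec_angle(v[1], v[2])
  }
  secs[[length(secs) + 1L]] <- list(p = J1, dir = bis(th[1], th[2]), hw = hw1)
  for (i in 2:(n_r - 1L)) {
    secs[[length(secs) + 1L]] <- list(
      p = pose$J[i, ], dir = bis(th[i], th[i + 1L]),
      hw = spec$widths[i + 1L] / 2)
  }
  # tail: taper from J_{n_r-1} to a point, slope ~0.18 for a clean peak
  tail_hw <- spec$widths[n_r] / 2
  tip <- pose$J[n_r - 1L, ] - (tail_hw / 0.18) * unit_vec(th[n_r])
  secs[[length(secs) + 1L]] <- list(p = tip, dir = th[n_r], hw = 0)
  right <- t(vapply(secs, function(s) s$p + s$hw * normal_vec(s$dir),
                    numeric(2)))
  left <- t(vapply(secs, function(s) s$p - s$hw * normal_vec(s$dir),
                   numeric(2)))
  # right side nose -> tail, then left side tail -> nose (apex and tail
  # cross-sections are degenerate and appear once)
  rbind(right, left[seq(nrow(left) - 1L, 2L), , drop = FALSE])
}

# Even-odd point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    if (y1 != y2) {
      cond <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cond)
    }
    j <- i
  }
  inside
}

# Linear pixel indices (into the arena matrix) of one fish's silhouette.
sim_fish_pixels <- function(pose, cfg) {
  h <- cfg$arena[1]
  w <- cfg$arena[2]
  poly <- sim_fish_outline(pose, cfg)
  x0 <- max(0L, as.integer(floor(min(poly[, 1]))))
  x1 <- min(w - 1L, as.integer(ceiling(max(poly[, 1]))))
  y0 <- max(0L, as.integer(floor(min(poly[, 2]))))
  y1 <- min(h - 1L, as.integer(ceiling(max(poly[, 2]))))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1
  ys <- y0:y1
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- points_in_polygon(px, py, poly)
  # linear index into an h x w matrix: row = y + 1, col = x + 1
  (px[inside]) * h + py[inside] + 1L
}

# --- scripted crossings ----------------------------------------------------

# Scripted crossings steer a fish pair through a brief overlap at a fixed
# zone point Z: fish `a` homes on Z with continuous speed control so that
# its snout passes Z at t_cross - 63.5 frames (its tail plus clearance
# then takes ~67.5 frames to clear at cruise speed); fish `b` first moves
# to a staging point perpendicular to a's approach, then homes on Z so
# that its snout arrives at t_cross, a few frames before a's tail has
# cleared. The resulting ~6-9 frame occlusion is long enough to terminate
# both trackers (> 5 lost frames) yet short enough that the relinking
# gates (gap < 6 frames) can reconnect the fragments.
script_lead <- 110L
script_tail <- 30L

# Per-frame scripted control for one fish in one event; returns the target
# heading and speed.
crossing_control <- function(role, t, ev, st) {
  nose <- st$nose
  if (role == "a") {
    # a's snout passes Z so that its tail tip reaches Z (body/speed = 60
    # frames later) just after b's snout arrives; the ~8-10 frame contact
    # then comes from the body widths crossing. a waits at a holding
    # point 160 px short of Z and dashes straight through it, so the
    # pass direction is well defined
    t_pass <- ev$frame - 57
    # the dash runway exceeds the body length, so at the crossing the
    # whole body (incl. the tail) lies on the straight dash line and the
    # tail-clearance timing is exact
    t_dash <- t_pass - 65
    if (t < t_dash) {
      H <- ev$Z - 260 * unit_vec(ev$adir)
      d <- H - nose
      dist <- sqrt(sum(d^2))
      list(target = if (dist > 15) vec_angle(d[1], d[2]) else st$heading,
           speed = min(6.5, max(1.5, dist / (t_dash - t))))
    } else if (t < t_pass - 1) {
      d <- ev$Z - nose
      dist <- sqrt(sum(d^2))
      list(target = if (dist > 15) vec_angle(d[1], d[2]) else st$heading,
           speed = 4)
    } else {
      list(target = st$heading, speed = 4)
    }
  } else {
    # b homes directly on Z, arriving at the crossing time
    if (t < ev$frame - 2) {
      d <- ev$Z - nose
      dist <- sqrt(sum(d^2))
      list(target = if (dist > 10) vec_angle(d[1], d[2]) else st$heading,
           speed = min(7, max(2, dist / (ev$frame - t))))
    } else {
      list(target = st$heading, speed = 4)
    }
  }
}

# --- main generator --------------------------------------------------------

#' Simulate an image sequence of articulated fish
#'
#' Generates ground-truth poses for every fish and frame, an occlusion log
#' measured from actual pairwise silhouette intersection, and a lazily
#' rendered frame sequence (frames are deterministic functions of the
#' configuration, so nothing large is held in memory).
#'
#' @param cfg a [sim_config()].
#' @return A `fish_sim` object: list with `config`, `truth` (tibble:
#'   `frame`, `id`, `nose_x`, `nose_y`, joint columns, `theta_*`), `events`
#'   (occlusion log tibble: `start_frame`, `end_frame`, `ids`), and
#'   `poses` (per-frame list of per-fish ground-truth pose geometry).
#'   Use [sim_frames()] to obtain the frame sequence and [sim_frame()] for
#'   a single rendered frame.
#' @export
simulate_fish <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_fish
  h <- cfg$arena[1]
  w <- cfg$arena[2]
  body <- sum(cfg$spec$lengths[-1]) + cfg$nose_len

  # spawn: prescribed positions/headings, or a jittered grid
  k <- ceiling(sqrt(n))
  cells <- expand.grid(gx = seq_len(k), gy = seq_len(k))
  cells <- cells[sample(nrow(cells), n), , drop = FALSE]
  margin <- cfg$wall_margin + body / 2
  fish <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(cfg$spawn)) {
      cx <- cfg$spawn[i, 1]
      cy <- cfg$spawn[i, 2]
      heading <- cfg$spawn[i, 3]
    } else {
      cx <- margin + (cells$gx[i] - 0.5) / k * (w - 2 * margin) +
        runif(1, -20, 20)
      cy <- margin + (cells$gy[i] - 0.5) / k * (h - 2 * margin) +
        runif(1, -20, 20)
      heading <- runif(1, -pi, pi)
    }
    fish[[i]] <- list(
      J1 = c(cx, cy), heading = heading, nose = c(cx, cy),
      speed = runif(1, cfg$speed[1], cfg$speed[2]),
      phase0 = runif(1, 0, 2 * pi),
      path = path_new(c(cx, cy), heading),
      script = NULL)
  }

  # expand crossing schedule
  scripts <- list()
  if (!is.null(cfg$crossings) && nrow(cfg$crossings) > 0L) {
    for (e in seq_len(nrow(cfg$crossings))) {
      scripts[[e]] <- list(frame = cfg$crossings$frame[e],
                           a = cfg$crossings$id1[e], b = cfg$crossings$id2[e],
                           plan = NULL, done = FALSE)
    }
  }

  # individual pigmentation: per-fish banding wavelength and phase give
  # each fish a mildly distinctive appearance, as the pigment patterns of
  # real fish do
  appearance <- lapply(seq_len(n), function(i) {
    list(lam = 36 + 6 * ((i - 1L) %% 5L), phase = 2.399 * i)
  })

  poses <- vector("list", cfg$n_frames)
  truth_rows <- vector("list", cfg$n_frames)
  overlap_frames <- list()   # per-frame list of overlapping pairs

  for (t in seq_len(cfg$n_frames)) {
    # -- scripted control ---------------------------------------------------
    for (e in seq_along(scripts)) {
      sc <- scripts[[e]]
      if (sc$done) next
      busy <- FALSE
      if (e > 1L) {
        for (e2 in seq_len(e - 1L)) {
          sc2 <- scripts[[e2]]
          if (!sc2$done && any(c(sc$a, sc$b) %in% c(sc2$a, sc2$b))) {
            busy <- TRUE
            break
          }
        }
      }
      if (t >= sc$frame - script_lead && is.null(sc$Z) && !busy) {
        # the crossing zone sits perpendicular off the line connecting
        # the pair: both routes are then equally long and meet at ~90
        # degrees instead of head-on; the crossing fires at its earliest
        # feasible time given the route lengths, so neither fish ever
        # has to loiter (a `frame` of 1 simply means "as soon as
        # possible")
        mid <- (fish[[sc$a]]$nose + fish[[sc$b]]$nose) / 2
        ab <- fish[[sc$b]]$nose - fish[[sc$a]]$nose
        perp <- normal_vec(vec_angle(ab[1], ab[2]))
        # prefer the perpendicular pointing towards the arena interior
        # (so the boundary clamp cannot push Z back onto the connecting
        # line), but flip to the other side when the interior candidate
        # is crowded by bystander fish and the outer one is clearly freer
        ctr2 <- c(w, h) / 2
        if (sum((ctr2 - mid) * perp) < 0) perp <- -perp
        clearance <- function(zz) {
          dmin <- Inf
          for (jj in seq_len(n)) {
            if (jj %in% c(sc$a, sc$b)) next
            dmin <- min(dmin, sqrt(sum((fish[[jj]]$nose - zz)^2)))
          }
          dmin
        }
        Zi <- mid + 300 * perp
        Zo <- mid - 300 * perp
        if (clearance(Zi) < 260 && clearance(Zo) > clearance(Zi) &&
            min(Zo[1], w - Zo[1], Zo[2], h - Zo[2]) > 350) {
          Z <- Zo
        } else {
          Z <- Zi
        }
        Z <- pmin(pmax(Z, 350), c(w, h) - 350)
        da <- Z - fish[[sc$a]]$nose
        adir <- vec_angle(da[1], da[2])
        scripts[[e]]$Z <- Z
        scripts[[e]]$adir <- adir
        d_a <- sqrt(sum(da^2))
        d_b <- sqrt(sum((Z - fish[[sc$b]]$nose)^2))
        scripts[[e]]$frame <- max(sc$frame,
                                  ceiling(t + (d_a - 260) / 4.5 + 124),
                                  ceiling(t + d_b / 4.7 + 4))
      }
      if (t > sc$frame + script_tail) {
        scripts[[e]]$done <- TRUE
        # participants keep cruising straight (with avoidance) after the
        # event so a staged scenario stays free of incidental encounters
        fish[[sc$a]]$cruise <- TRUE
        fish[[sc$b]]$cruise <- TRUE
      }
    }

    scripted <- rep(FALSE, n)
    for (i in seq_len(n)) {
      st <- fish[[i]]
      # steering: scripted control > wall avoidance + separation + noise
      ctrl <- NULL
      role <- NULL
      for (e in seq_along(scripts)) {
        sc <- scripts[[e]]
        if (sc$done || is.null(sc$Z)) next
        if (i == sc$a || i == sc$b) {
          ctrl <- sc
          role <- if (i == sc$a) "a" else "b"
          break
        }
      }
      st$und_scale <- 1
      if (!is.null(ctrl)) {
        scripted[i] <- TRUE
        # glide through the crossing window: ramp the tail beat off and
        # back on around it
        tc <- ctrl$frame
        st$und_scale <- if (t >= tc - 65 && t <= tc + 10) 0
          else if (t > tc - 80 && t < tc - 65) (tc - 65 - t) / 15
          else if (t > tc + 10 && t < tc + 25) (t - tc - 10) / 15
          else 1
        cc <- crossing_control(role, t, ctrl, st)
        target <- cc$target
        # emergency avoidance of third parties while en route (the homing
        # re-solves its timing each frame, so a brief detour is absorbed
        # by the speed control); the partner is never avoided -- the
        # staged geometry keeps the pair apart until the crossing
        partner <- if (role == "a") ctrl$b else ctrl$a
        if (t < ctrl$frame - 20 || t > ctrl$frame + 8) {
          excl <- c(i, partner)
          nd2 <- Inf
          np2 <- NULL
          for (jj in seq_len(n)) {
            if (jj %in% excl) next
            pts <- if (!is.null(fish[[jj]]$pose)) {
              rbind(fish[[jj]]$pose$N, fish[[jj]]$pose$J[4, ],
                    fish[[jj]]$pose$O)
            } else {
              matrix(fish[[jj]]$nose, 1)
            }
            dds <- sqrt(rowSums((pts - matrix(st$nose, nrow(pts), 2,
                                              byrow = TRUE))^2))
            if (min(dds) < nd2) {
              nd2 <- min(dds)
              np2 <- pts[which.min(dds), ]
            }
          }
          if (is.finite(nd2) && nd2 < 190) {
            away <- st$nose - np2
            target <- vec_angle(away[1], away[2])
          }
        }
        st$speed <- cc$speed
        turn <- wrap_angle(target - st$heading)
        st$heading <- st$heading +
          sign(turn) * min(abs(turn), 1.5 * cfg$turn_max)
      } else if (isTRUE(st$cruise)) {
        # post-event cruise: disperse radially outward, dodging other
        # fish; the boundary clamp parks the fish when it reaches a wall
        rad <- st$nose - c(w, h) / 2
        target <- if (sqrt(sum(rad^2)) > 1) vec_angle(rad[1], rad[2])
                  else st$heading
        nd2 <- Inf
        np2 <- NULL
        for (jj in seq_len(n)) {
          if (jj == i) next
          pts <- if (!is.null(fish[[jj]]$pose)) {
            rbind(fish[[jj]]$pose$N, fish[[jj]]$pose$J[4, ], fish[[jj]]$pose$O)
          } else {
            matrix(fish[[jj]]$nose, 1)
          }
          dds <- sqrt(rowSums((pts - matrix(st$nose, nrow(pts), 2,
                                            byrow = TRUE))^2))
          if (min(dds) < nd2) {
            nd2 <- min(dds)
            np2 <- pts[which.min(dds), ]
          }
        }
        if (is.finite(nd2) && nd2 < 190) {
          away <- st$nose - np2
          target <- vec_angle(away[1], away[2])
        }
        turn <- wrap_angle(target - st$heading)
        st$heading <- st$heading + sign(turn) * min(abs(turn), cfg$turn_max)
      } else {
        # separation first: steer away from the nearest point of any other
        # fish's body chain (and away from any active scripted crossing
        # zone, so bystanders do not blunder into a staged encounter)
        probe <- st$nose + 30 * unit_vec(st$heading)
        nd <- Inf
        npt <- NULL
        for (e in seq_along(scripts)) {
          if (scripts[[e]]$done || is.null(scripts[[e]]$Z)) next
          dP <- sqrt(sum((probe - scripts[[e]]$Z)^2))
          if (dP < nd) {
            nd <- dP
            npt <- scripts[[e]]$Z
          }
        }
        for (jj in seq_len(n)) {
          if (jj == i) next
          pts <- if (!is.null(fish[[jj]]$pose)) {
            rbind(fish[[jj]]$pose$N, fish[[jj]]$pose$J, fish[[jj]]$pose$O)
          } else {
            rbind(fish[[jj]]$nose,
                  fish[[jj]]$path$pts[nrow(fish[[jj]]$path$pts), ])
          }
          dists <- sqrt(rowSums((pts - matrix(probe, nrow(pts), 2,
                                              byrow = TRUE))^2))
          if (min(dists) < nd) {
            nd <- min(dists)
            npt <- pts[which.min(dists), ]
          }
        }
        # wall avoidance dominates (being pushed into a wall by another
        # fish must not happen); an emergency double turn rate guarantees
        # a head-on approach at top speed still clears the wall
        nose_ahead <- st$nose + 60 * unit_vec(st$heading)
        wall_dist <- min(nose_ahead[1], w - nose_ahead[1],
                         nose_ahead[2], h - nose_ahead[2])
        steer <- 0
        max_turn <- cfg$turn_max
        if (wall_dist < cfg$wall_margin) {
          ctr <- c(w, h) / 2
          d <- ctr - st$nose
          want <- wrap_angle(vec_angle(d[1], d[2]) - st$heading)
          if (wall_dist < cfg$wall_margin - 50) max_turn <- 2 * cfg$turn_max
          steer <- sign(want) * min(abs(want), max_turn)
        }
        if (is.finite(nd) && nd < cfg$sep_radius) {
          away <- probe - npt
          want <- wrap_angle(vec_angle(away[1], away[2]) - st$heading)
          steer <- steer + sign(want) * min(abs(want), cfg$turn_max)
        }
        turn <- steer + max(-cfg$turn_max, min(cfg$turn_max,
                                               rnorm(1, 0, cfg$turn_sd)))
        st$heading <- st$heading + max(-max_turn, min(max_turn, turn))
      }
      # advance; the boundary backstop clamps the position (the fish
      # slides along the wall while its steering turns it away) so the
      # path never hairpins and silhouettes are never clipped
      J1n <- st$path$pts[nrow(st$path$pts), ] + st$speed * unit_vec(st$heading)
      lo <- cfg$nose_len + 25
      J1n[1] <- min(max(J1n[1], lo), w - lo)
      J1n[2] <- min(max(J1n[2], lo), h - lo)
      st$J1 <- J1n
      st$path <- path_push(st$path, st$J1)
      ps <- sim_pose(st$path, t, cfg, st$phase0, st$und_scale)
      st$nose <- ps$N
      st$pose <- ps
      fish[[i]] <- st
    }

    poses[[t]] <- lapply(fish, `[[`, "pose")

    # occlusion log: actual pairwise silhouette intersection
    pix <- lapply(poses[[t]], sim_fish_pixels, cfg = cfg)
    pairs <- list()
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (length(intersect(pix[[i]], pix[[j]]))) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      }
    }
    overlap_frames[[t]] <- pairs

    truth_rows[[t]] <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      ps <- poses[[t]][[i]]
      row <- c(frame = t, id = i, nose_x = ps$N[1], nose_y = ps$N[2],
               G_x = ps$G[1], G_y = ps$G[2])
      jv <- as.vector(t(ps$J))
      names(jv) <- as.vector(t(outer(seq_len(nrow(ps$J)), c("x", "y"),
                                     function(a, b) paste0("J", a, "_", b))))
      tv <- ps$theta
      names(tv) <- paste0("theta_", seq_along(tv))
      as_tibble(as.list(c(row, jv, O_x = ps$O[1], O_y = ps$O[2], tv)))
    }))
  }

  events <- collapse_overlaps(overlap_frames)
  # pre-generated sensor-noise field; each frame applies it at a
  # frame-specific cyclic shift, which keeps frames deterministic and
  # their noise patterns mutually decorrelated at patch scale without
  # drawing millions of variates per rendered frame
  set.seed((cfg$seed * 7919L + 13L) %% .Machine$integer.max)
  noise <- matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)
  structure(list(config = cfg, truth = dplyr::bind_rows(truth_rows),
                 events = events, poses = poses, appearance = appearance,
                 noise = noise, scripts = scripts),
            class = "fish_sim")
}

# Collapse per-frame overlapping pairs into contiguous per-pair events.
collapse_overlaps <- function(overlap_frames) {
  keys <- list()
  for (t in seq_along(overlap_frames)) {
    for (p in overlap_frames[[t]]) {
      k <- paste(p, collapse = "-")
      keys[[k]] <- c(keys[[k]], t)
    }
  }
  if (!length(keys)) {
    return(tibble(start_frame = integer(0), end_frame = integer(0),
                  ids = list()))
  }
  rows <- list()
  for (k in names(keys)) {
    fr <- sort(unique(keys[[k]]))
    brk <- c(0, which(diff(fr) > 1), length(fr))
    ids <- as.integer(strsplit(k, "-")[[1]])
    for (b in seq_len(length(brk) - 1L)) {
      span <- fr[(brk[b] + 1L):brk[b + 1L]]
      rows[[length(rows) + 1L]] <-
        tibble(start_frame = span[1], end_frame = span[length(span)],
               ids = list(ids))
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start_frame)
}

#' Ground-truth geometry of a fish at a prescribed pose
#'
#' Builds the generator's pose record (joints, nose, head/tail midpoints)
#' from an explicit head-joint position and per-segment orientations, and
#' optionally renders its silhouette. Useful for controlled experiments
#' (straight or S-curved fish at known poses).
#'
#' @param J1 head joint position (x, y), pixels.
#' @param theta per-segment orientations, radians (length `spec$n_r`).
#' @param cfg a [sim_config()] (arena and body shape parameters).
#' @return A list with `pose` (generator pose record: `J`, `theta`, `N`,
#'   `G`, `O`) and `mask` (logical silhouette raster of the arena size).
#' @export
synthetic_fish <- function(J1, theta, cfg) {
  spec <- cfg$spec
  n_r <- spec$n_r
  stopifnot(length(theta) == n_r)
  J <- matrix(0, n_r - 1L, 2L)
  J[1, ] <- J1
  for (i in 2:(n_r - 1L)) {
    J[i, ] <- J[i - 1L, ] - spec$lengths[i] * unit_vec(theta[i])
  }
  u1 <- unit_vec(theta[1])
  O <- J[n_r - 1L, ] - spec$lengths[n_r] * unit_vec(theta[n_r])
  pose <- list(J = J, theta = theta, N = J1 + cfg$nose_len * u1,
               G = J1 + spec$lengths[1] * u1, O = O)
  mask <- matrix(FALSE, cfg$arena[1], cfg$arena[2])
  mask[sim_fish_pixels(pose, cfg)] <- TRUE
  list(pose = pose, mask = mask)
}

#' Render one simulated frame
#'
#' Deterministic for a given configuration and frame index: the pixel noise
#' stream is seeded from the simulation seed and the frame number.
#'
#' @param sim a `fish_sim` from [simulate_fish()].
#' @param t frame index.
#' @return A grayscale matrix (0-255).
#' @export
sim_frame <- function(sim, t) {
  cfg <- sim$config
  h <- cfg$arena[1]
  w <- cfg$arena[2]
  img <- matrix(cfg$plate, h, w)
  for (i in seq_along(sim$poses[[t]])) {
    pose <- sim$poses[[t]][[i]]
    idx <- sim_fish_pixels(pose, cfg)
    if (cfg$stripe_amp > 0) {
      # per-fish pigment pattern anchored to the nose (the head is rigid,
      # so the pattern is carried rigidly with the fish): dark blotches at
      # fish-specific distances plus a faint stripe
      ap <- sim$appearance[[i]]
      px <- (idx - 1L) %/% h
      py <- (idx - 1L) %% h
      d <- sqrt((px - pose$N[1])^2 + (py - pose$N[2])^2)
      # smooth pigment banding: wavelengths long against the few-px patch
      # placement jitter (so the same fish correlates with itself across
      # frames), fish-specific wavelength and phase
      img[idx] <- cfg$fish_gray +
        cfg$stripe_amp * sin(2 * pi * d / ap$lam + ap$phase)
    } else {
      img[idx] <- cfg$fish_gray
    }
  }
  if (cfg$noise_sd > 0 && !is.null(sim$noise)) {
    dr <- (t * 131L) %% h
    dc <- (t * 197L) %% w
    ri <- c((dr + 1L):h, seq_len(dr))[seq_len(h)]
    ci <- c((dc + 1L):w, seq_len(dc))[seq_len(w)]
    img <- img + sim$noise[ri, ci]
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  img
}

#' Lazy frame sequence of a simulation
#'
#' @param sim a `fish_sim`.
#' @return A `frame_seq` object usable wherever a list of frames is
#'   accepted ([estimate_background()], [track_sequence()], ...).
#' @export
sim_frames <- function(sim) {
  structure(list(sim = sim, n = sim$config$n_frames), class = "frame_seq")
}

# Frame-sequence accessors: a frame source is either a plain list of
# matrices or a lazy `frame_seq`.
frames_length <- function(frames) {
  if (inherits(frames, "frame_seq")) frames$n else length(frames)
}

frame_get <- function(frames, i) {
  if (inherits(frames, "frame_seq")) sim_frame(frames$sim, i) else frames[[i]]
}

#' Background image of a simulation
#'
#' The true fish-free plate (before noise), useful as the known background
#' in controlled experiments.
#'
#' @param sim a `fish_sim`.
#' @return A constant matrix at the plate intensity.
#' @export
sim_background <- function(sim) {
  matrix(sim$config$plate, sim$config$arena[1], sim$config$arena[2])
}
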