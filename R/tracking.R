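# Two-stage per-frame tracking: Kalman prediction/update of the head state
# with Kuhn-Munkres association under an NCC x von Mises cost, tracker
# lifecycle rules, and body-chain refitting that vetoes bad head tracks.

#' Constant-velocity Kalman model for the head state
#'
#' The 6-dimensional state is `[x, y, theta, x', y', theta']` where (x, y)
#' is the head joint `J1` and primes denote the previous frame. The
#' transition realizes the constant-velocity recursion
#' `x_t = 2 x_{t-1} - x_{t-2}`; the observation picks out the current
#' position and orientation.
#'
#' @param q diagonal of the state-noise covariance `Q`
#'   (px^2, px^2, rad^2 for position and orientation blocks).
#' @param r diagonal of the observation-noise covariance `R`.
#' @param p0_scale initial covariance is `p0_scale * Q`; kept tight so that
#'   a gross mis-association of a young tracker cannot jump its state all
#'   the way onto another fish (the body-fit veto then catches it).
#' @return A `kalman_model` list with `F`, `H`, `Q`, `R`, `P0`.
#' @export
kalman_model <- function(q = c(1, 1, 0.01), r = c(2, 2, 0.02), p0_scale = 1) {
  I3 <- diag(3)
  Fm <- rbind(cbind(2 * I3, -I3), cbind(I3, matrix(0, 3, 3)))
  H <- cbind(I3, matrix(0, 3, 3))
  Q <- diag(rep(q, 2))
  R <- diag(r)
  structure(list(F = Fm, H = H, Q = Q, R = R, P0 = p0_scale * Q),
            class = "kalman_model")
}

# Apply the transition to a state vector with angle wrapping: the predicted
# orientation is theta + wrapped angular velocity.
transition_state <- function(X) {
  Xh <- c(2 * X[1:2] - X[4:5],
          wrap_angle(X[3] + wrap_angle(X[3] - X[6])),
          X[1:3])
  Xh
}

#' Kalman prediction of a head state
#'
#' @param X 6-vector state.
#' @param P 6x6 covariance.
#' @param km a [kalman_model()].
#' @return `list(X, P)` with the prior state and covariance.
#' @export
kalman_predict <- function(X, P, km) {
  list(X = transition_state(X), P = km$F %*% P %*% t(km$F) + km$Q)
}

#' Kalman measurement update of a head state
#'
#' Standard update with the orientation innovation wrapped to (-pi, pi].
#'
#' @param Xh,Ph prior state and covariance from [kalman_predict()].
#' @param km a [kalman_model()].
#' @param Z observation `[x, y, theta]`.
#' @return `list(X, P)` posterior.
#' @export
kalman_update <- function(Xh, Ph, km, Z) {
  S <- km$H %*% Ph %*% t(km$H) + km$R
  if (abs(det(S)) < .Machine$double.xmin) {
    if (all(km$R == 0)) {
      # exact-measurement limit (R -> 0): the observed components follow
      # the measurement identically
      X <- Xh
      X[1:3] <- Z
      X[3] <- wrap_angle(X[3])
      return(list(X = X, P = Ph))
    }
    stop("singular innovation covariance: R must be positive definite")
  }
  K <- Ph %*% t(km$H) %*% solve(S)
  innov <- Z - as.vector(km$H %*% Xh)
  innov[3] <- wrap_angle(innov[3])
  X <- as.vector(Xh + K %*% innov)
  X[3] <- wrap_angle(X[3])
  X[6] <- wrap_angle(X[6])
  P <- (diag(6) - K %*% km$H) %*% Ph
  list(X = X, P = P)
}

#' Normalized cross-correlation of two image patches
#'
#' Energy-normalized (not zero-mean) cross-correlation,
#' `sum(I I') / sqrt(sum(I^2) sum(I'^2))`; for nonnegative images the value
#' lies in \[0, 1\] and is invariant to a global intensity scaling. A
#' zero-mean variant is available behind `zero_mean` but is off by default.
#' Patches of unequal size are resampled to the first patch's dimensions.
#'
#' @param a,b numeric matrices.
#' @param zero_mean subtract patch means first.
#' @return Similarity value; 0 if either patch has no energy.
#' @export
ncc <- function(a, b, zero_mean = FALSE) {
  if (!identical(dim(a), dim(b))) b <- resize_patch(b, dim(a))
  if (zero_mean) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Nearest-neighbor resampling of a patch to target dims c(h, w).
resize_patch <- function(p, d) {
  ri <- pmax(1L, round(seq(1, nrow(p), length.out = d[1])))
  ci <- pmax(1L, round(seq(1, ncol(p), length.out = d[2])))
  p[ri, ci, drop = FALSE]
}

#' Von Mises density
#'
#' Circular analogue of the Gaussian used both to score orientation
#' agreement in the association cost and to sample candidate segment angles
#' in body tracking: `exp(k cos(y - mu)) / (2 pi I0(k))`.
#'
#' @param y,mu angles in radians (difference is wrapped).
#' @param k concentration (> 0).
#' @return Density value(s).
#' @export
von_mises_density <- function(y, mu, k) {
  exp(k * cos(wrap_angle(y - mu))) / (2 * pi * besselI(k, 0))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param k concentration; `k = 0` gives the uniform circular distribution.
#' @return `n` angles wrapped to (-pi, pi].
#' @export
rvon_mises <- function(n, mu, k) {
  if (k <= 0) return(wrap_angle(runif(n, 0, 2 * pi)))
  a <- 1 + sqrt(1 + 4 * k^2)
  b <- (a - sqrt(2 * a)) / (2 * k)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- k * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

#' Association cost between a predicted tracker and a measurement
#'
#' `exp(-(NCC + V))` where NCC compares the tracker's stored head patch
#' with the measurement's patch and V is the von Mises similarity between
#' the predicted head orientation and the measured one. If either term
#' falls below its gate the pair is forbidden (`Inf`).
#'
#' @param patch_i tracker's last associated head patch.
#' @param theta_pred predicted head orientation, radians.
#' @param patch_j,theta_j measurement patch and orientation.
#' @param k von Mises concentration.
#' @param thr_ncc,thr_v gating thresholds on NCC and V.
#' @return Scalar cost in (0, 1\] or `Inf`.
#' @export
association_cost <- function(patch_i, theta_pred, patch_j, theta_j,
                             k = 4, thr_ncc = 0.6, thr_v = 0.05) {
  s <- ncc(patch_i, patch_j)
  v <- von_mises_density(theta_pred, theta_j, k)
  if (s < thr_ncc || v < thr_v) return(Inf)
  exp(-(s + v))
}

# --- tracker lifecycle -----------------------------------------------------

new_tracker <- function(id, obs, pose, frame, km) {
  Z <- c(obs$J1, obs$theta1)
  pose$id <- id
  pose$frame <- frame
  list(id = id,
       X = c(Z, Z),            # duplicated first observation: zero velocity
       P = km$P0,
       patch = obs$patch,
       lost = 0L,
       frames = frame,
       observed = TRUE,
       states = matrix(Z, nrow = 1L),
       poses = list(pose),
       last_pose = pose)
}

#' Coast an unassociated tracker
#'
#' Propagates the head state by linear extrapolation from the previous two
#' frames (with wrapped orientation) and increments the lost counter.
#'
#' @param tr a tracker record.
#' @param km a [kalman_model()].
#' @param frame current frame index.
#' @return The updated tracker.
#' @export
coast <- function(tr, km, frame) {
  pr <- kalman_predict(tr$X, tr$P, km)
  tr$X <- pr$X
  tr$P <- pr$P
  tr$lost <- tr$lost + 1L
  tr$frames <- c(tr$frames, frame)
  tr$observed <- c(tr$observed, FALSE)
  tr$states <- rbind(tr$states, tr$X[1:3])
  tr$poses <- c(tr$poses, list(NULL))
  tr
}

#' Refit the body chain of a tracked fish
#'
#' Same greedy chain fitting as in detection, but candidate angles for each
#' segment are drawn from a von Mises distribution centered on that
#' segment's orientation in the previous frame's pose, exploiting motion
#' continuity. Falls back to uniform draws when no previous pose exists. A
#' cover ratio below `cover_min` flags the pose invalid, which terminates
#' the tracker (the body-fit veto).
#'
#' @param J1 tracked head joint for this frame.
#' @param theta1 tracked head orientation.
#' @param region foreground region (logical matrix or 2-column 0-based
#'   coordinate matrix).
#' @param prev_pose the fish's pose in the previous frame, or NULL.
#' @param spec a [rect_spec()].
#' @param n_pb candidate angles per segment.
#' @param k_body von Mises concentration of the candidate draws.
#' @param cover_min minimum admissible cover ratio.
#' @param nose_margin nose-to-front-edge margin, px.
#' @return A [fish_pose()] with attribute `valid`.
#' @export
track_body <- function(J1, theta1, region, prev_pose, spec, n_pb = 256,
                       k_body = 4, cover_min = 0.8, nose_margin = 10) {
  region_xy <- region_coords(region)
  angle_fun <- if (is.null(prev_pose)) {
    function(i) runif(n_pb, 0, 2 * pi)
  } else {
    function(i) rvon_mises(n_pb, prev_pose$theta[i], k_body)
  }
  fit_chain(J1, theta1, spec, region_xy, n_pb, angle_fun,
            cover_min = cover_min, nose_margin = nose_margin)
}

# Foreground region (0-based coords) of the component containing, or within
# `radius` px of, point p. `labeled` is a label_components() result.
# Returns a 0-row matrix when no component is near.
region_near_point <- function(labeled, p, radius = 2L) {
  labmat <- labeled$labels
  h <- nrow(labmat)
  w <- ncol(labmat)
  x <- as.integer(round(p[1]))
  y <- as.integer(round(p[2]))
  lab <- 0L
  for (r in 0:radius) {
    xs <- max(0L, x - r):min(w - 1L, x + r)
    ys <- max(0L, y - r):min(h - 1L, y + r)
    sub <- labmat[ys + 1L, xs + 1L, drop = FALSE]
    nz <- sub[sub > 0L]
    if (length(nz)) {
      lab <- nz[1]
      break
    }
  }
  if (lab == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  if (!is.null(labeled$coords)) {
    labeled$coords[[as.character(lab)]]
  } else {
    component_coords(labmat, lab)
  }
}

#' Advance all trackers by one frame
#'
#' Runs the full per-frame tracking cycle: Kalman prediction, gated
#' NCC x von Mises cost matrix, Kuhn-Munkres association, measurement
#' update plus body refit for associated trackers (with the body-fit veto),
#' coasting for unassociated trackers, lifecycle termination rules
#' (`lost > lost_max` or an unassociated track shorter than 2 frames, which
#' is discarded entirely), and spawning of new trackers from unassociated
#' measurements.
#'
#' @param trackers list of live tracker records.
#' @param detections list of detections from [detect_frame()].
#' @param labeled component labeling of this frame's foreground mask (a
#'   [label_components] result, or a bare integer label matrix).
#' @param frame frame index.
#' @param params parameter list from [fishchain_config()].
#' @param km a [kalman_model()].
#' @param next_id next fresh identity label.
#' @param force_pairs optional 2-column matrix of (tracker index,
#'   measurement index) pairs overriding the data association; used to
#'   study the body-fit veto under forced wrong associations.
#' @return `list(trackers, finished, next_id)` where `finished` collects
#'   tracker records terminated this frame (with a `reason` field).
#' @export
step_frame <- function(trackers, detections, labeled, frame, params, km,
                       next_id, force_pairs = NULL) {
  if (is.matrix(labeled)) labeled <- list(labels = labeled)
  n <- length(trackers)
  m <- length(detections)
  finished <- list()

  # predict
  preds <- lapply(trackers, function(tr) kalman_predict(tr$X, tr$P, km))

  # associate
  if (!is.null(force_pairs)) {
    pairs <- force_pairs
    un_rows <- setdiff(seq_len(n), pairs[, 1])
    un_cols <- setdiff(seq_len(m), pairs[, 2])
  } else if (n > 0L && m > 0L) {
    C <- matrix(Inf, n, m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        C[i, j] <- association_cost(trackers[[i]]$patch, preds[[i]]$X[3],
                                    detections[[j]]$head$patch,
                                    detections[[j]]$head$theta1,
                                    params$k, params$thr_ncc, params$thr_v)
      }
    }
    asg <- associate(C)
    pairs <- asg$pairs
    un_rows <- asg$unassigned_rows
    un_cols <- asg$unassigned_cols
  } else {
    pairs <- matrix(integer(0), ncol = 2L)
    un_rows <- seq_len(n)
    un_cols <- seq_len(m)
  }

  keep <- logical(n)
  vetoed_meas <- integer(0)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]
      j <- pairs[r, 2]
      tr <- trackers[[i]]
      obs <- detections[[j]]$head
      up <- kalman_update(preds[[i]]$X, preds[[i]]$P, km,
                          c(obs$J1, obs$theta1))
      J1 <- up$X[1:2]
      region <- region_near_point(labeled, J1, params$region_radius)
      pose <- track_body(J1, up$X[3], region, tr$last_pose, params$spec,
                         params$n_pb, params$k_body, params$cover_min,
                         params$nose_margin)
      if (!isTRUE(attr(pose, "valid"))) {
        # body-fit veto: the head track is implausible, terminate; the
        # measurement itself was a valid detection and is now effectively
        # unassociated, so it seeds a new tracker below
        tr$reason <- "body_fit"
        finished[[length(finished) + 1L]] <- tr
        vetoed_meas <- c(vetoed_meas, j)
        next
      }
      pose$frame <- frame
      pose$id <- tr$id
      tr$X <- up$X
      tr$P <- up$P
      tr$patch <- obs$patch
      tr$lost <- 0L
      tr$frames <- c(tr$frames, frame)
      tr$observed <- c(tr$observed, TRUE)
      tr$states <- rbind(tr$states, tr$X[1:3])
      tr$poses <- c(tr$poses, list(pose))
      tr$last_pose <- pose
      trackers[[i]] <- tr
      keep[i] <- TRUE
    }
  }

  for (i in un_rows) {
    tr <- trackers[[i]]
    if (sum(tr$observed) < 2L) {
      # too short to be a real fish: a tracking error, dropped entirely
      tr$reason <- "error"
      next
    }
    tr <- coast(tr, km, frame)
    if (tr$lost > params$lost_max) {
      tr$reason <- "lost"
      finished[[length(finished) + 1L]] <- tr
    } else {
      trackers[[i]] <- tr
      keep[i] <- TRUE
    }
  }

  trackers <- trackers[keep]

  for (j in c(un_cols, vetoed_meas)) {
    det <- detections[[j]]
    trackers[[length(trackers) + 1L]] <-
      new_tracker(next_id, det$head, det$pose, frame, km)
    next_id <- next_id + 1L
  }

  list(trackers = trackers, finished = finished, next_id = next_id)
}

# Convert a (finished or live) tracker record into a tracklet.
finalize_tracklet <- function(tr) {
  obs_idx <- which(tr$observed)
  structure(list(
    id = tr$id,
    st = tr$frames[1],
    ed = tr$frames[length(tr$frames)],
    frames = tr$frames,
    observed = tr$observed,
    states = tr$states,
    poses = tr$poses[obs_idx],
    head_in = tr$states[1, ],
    head_out = tr$states[nrow(tr$states), ],
    n_obs = length(obs_idx),
    reason = if (is.null(tr$reason)) "end" else tr$reason
  ), class = "tracklet")
}

#' Track a full frame sequence
#'
#' Alternates detection and tracking over all frames, producing the set of
#' tracklets that the relinking stage reconnects. Per-frame randomness
#' (chain-fitting candidate draws) is restarted from a seed derived from
#' `seed` and the frame index, making runs reproducible.
#'
#' @param frames list of grayscale matrices.
#' @param background background matrix (or NULL to estimate it from the
#'   frames).
#' @param params parameter list from [fishchain_config()].
#' @param seed integer seed for the per-frame RNG streams.
#' @return A list of `tracklet` objects.
#' @export
track_sequence <- function(frames, background = NULL,
                           params = fishchain_config(), seed = 1L) {
  if (is.null(background)) background <- estimate_background(frames)
  km <- kalman_model(params$kalman_q, params$kalman_r, params$kalman_p0)
  trackers <- list()
  tracklets <- list()
  next_id <- 1L
  for (f in seq_len(frames_length(frames))) {
    img <- frame_get(frames, f)
    set.seed((seed * 1009L + f) %% .Machine$integer.max)
    mask <- segment_foreground(img, background, params$threshold)
    lc <- label_components(mask, params$min_area)
    detections <- detect_frame(img, background, params, labeled = lc)
    st <- step_frame(trackers, detections, lc, f, params, km, next_id)
    trackers <- st$trackers
    next_id <- st$next_id
    for (tr in st$finished) {
      # the "shorter than 2 frames" removal applies to unassociated
      # tracking errors; a veto-terminated tracker's earlier poses were
      # valid detections and stay in the results
      if (tr$reason != "error" && sum(tr$observed) >= 1L) {
        tracklets[[length(tracklets) + 1L]] <- finalize_tracklet(tr)
      }
    }
  }
  for (tr in trackers) {
    if (sum(tr$observed) >= 1L) {
      tracklets[[length(tracklets) + 1L]] <- finalize_tracklet(tr)
    }
  }
  tracklets
}

#' Tabulate tracklet poses
#'
#' @param tracklets list of tracklets from [track_sequence()].
#' @param spec a [rect_spec()].
#' @return A tibble of pose rows with tracklet `st`/`ed` columns appended.
#' @export
tracklets_to_table <- function(tracklets, spec) {
  tabs <- lapply(tracklets, function(tk) {
    tab <- poses_to_table(tk$poses, spec)
    tab$st <- tk$st
    tab$ed <- tk$ed
    tab
  })
  dplyr::bind_rows(tabs)
}
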