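test_that("background estimation averages frames", {
  f1 <- matrix(10, 20, 20)
  f2 <- matrix(20, 20, 20)
  expect_equal(estimate_background(list(f1)), f1)
  expect_equal(estimate_background(list(f1, f2)), matrix(15, 20, 20))
  expect_error(estimate_background(list(f1, matrix(0, 10, 10))), "dimensions")
})

test_that("background from a moving-fish sequence recovers the plate", {
  cfg <- sim_config(n_fish = 1, arena = c(512L, 512L), n_frames = 60,
                    seed = 7, noise_sd = 0, wall_margin = 100)
  sim <- simulate_fish(cfg)
  bg <- estimate_background(sim_frames(sim))
  # wherever the fish dwelled in less than 20% of frames the mean is
  # within 3 gray levels of the true plate
  occ <- matrix(0, 512, 512)
  for (t in seq_len(60)) {
    occ[fishchain:::sim_fish_pixels(sim$poses[[t]][[1]], cfg)] <-
      occ[fishchain:::sim_fish_pixels(sim$poses[[t]][[1]], cfg)] + 1
  }
  # the mean offsets the plate by dwell_fraction * contrast, so pixels
  # visited in < 2% of frames stay within ~3 gray levels of the plate
  rare <- occ / 60 < 0.019
  expect_true(all(abs(bg[rare] - cfg$plate) < 3.3))
  # direct-mean oracle
  direct <- Reduce(`+`, lapply(1:60, function(t) sim_frame(sim, t))) / 60
  expect_equal(bg, direct, tolerance = 1e-12)
})

test_that("foreground segmentation thresholds the background difference", {
  bg <- matrix(200, 64, 64)
  expect_false(any(segment_foreground(bg, bg, 50)))
  frame <- bg
  frame[20:30, 20:40] <- 40
  mask <- segment_foreground(frame, bg, 50)
  expect_equal(sum(mask), 11 * 21)
  expect_false(any(segment_foreground(frame, bg, 255)))
})

test_that("boundary extraction resamples components at unit arc spacing", {
  mask <- matrix(FALSE, 200, 200)
  mask[50:69, 40:139] <- TRUE  # 100 x 20 rectangle
  curves <- extract_boundary(mask, spacing = 1, min_area = 10)
  expect_length(curves, 1L)
  n <- nrow(curves[[1]]$B)
  expect_gt(n, 0.95 * 236)
  expect_lt(n, 1.05 * 240)
  seg <- sqrt(rowSums(diff(curves[[1]]$B)^2))
  expect_lt(max(abs(seg - curves[[1]]$spacing)), 0.5)

  # filled disk: circumference 2 pi r
  mask2 <- matrix(FALSE, 200, 200)
  xy <- expand.grid(x = 1:200, y = 1:200)
  inside <- (xy$x - 100)^2 + (xy$y - 100)^2 <= 30^2
  mask2[cbind(xy$y[inside], xy$x[inside])] <- TRUE
  curves2 <- extract_boundary(mask2, 1, 10)
  expect_equal(nrow(curves2[[1]]$B), 2 * pi * 30, tolerance = 0.07)

  # two disjoint blobs give two curves
  mask3 <- mask
  mask3[120:139, 40:139] <- TRUE
  expect_length(extract_boundary(mask3, 1, 10), 2L)
})

test_that("discrete curvature matches the analytic circle value", {
  # exact circle of radius 20 resampled at unit arc spacing
  n <- round(2 * pi * 20)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cur <- structure(list(B = cbind(100 + 20 * cos(ang), 100 - 20 * sin(ang)),
                        spacing = 2 * pi * 20 / n),
                   class = "boundary_curve")
  prof <- compute_curvature(cur, neighbor_arc = 8)
  expect_true(all(abs(abs(prof$C) - 1 / 20) < 0.1 / 20))
  # counter-clockwise convex curve bends left everywhere
  expect_true(all(prof$C > 0))
  expect_equal(sum(prof$C) * prof$spacing, 2 * pi, tolerance = 0.05)

  # a rasterized disk boundary is noisier, but stays convex with the
  # exact discrete total turning
  mask <- matrix(FALSE, 200, 200)
  xy <- expand.grid(x = 1:200, y = 1:200)
  inside <- (xy$x - 100)^2 + (xy$y - 100)^2 <= 20^2
  mask[cbind(xy$y[inside], xy$x[inside])] <- TRUE
  curd <- extract_boundary(mask, 1, 10)[[1]]
  profd <- compute_curvature(curd, 8)
  expect_true(all(profd$C > 0))
  expect_equal(sum(profd$C) * profd$spacing, 2 * pi, tolerance = 0.05)
  expect_equal(median(profd$C), 0.05, tolerance = 0.15)
  expect_error(compute_curvature(list(B = curd$B[1:10, ], spacing = 1), 8),
               "short")
})

test_that("straight boundary segments have near-zero curvature", {
  mask <- matrix(FALSE, 200, 300)
  mask[80:119, 50:249] <- TRUE
  cur <- extract_boundary(mask, 1, 10)[[1]]
  prof <- compute_curvature(cur, 8)
  # most points lie on long straight edges
  expect_gt(mean(abs(prof$C) < 1e-6), 0.7)
})

test_that("nose and tail are found on a synthetic fish, none on a circle", {
  ff <- fish_frame(s_curve_theta(0.9))
  mask <- segment_foreground(ff$img, ff$bg, 80)
  cur <- extract_boundary(mask, 1, 100)[[1]]
  prof <- compute_curvature(cur, 8)
  cands <- find_nose_tail(prof, 0.08, 40, curve = cur)
  expect_length(cands, 1L)
  expect_false(is.na(cands[[1]]$tail))
  nose_pt <- fishchain:::boundary_at(cur$B, cands[[1]]$nose)
  expect_lt(sqrt(sum((nose_pt - ff$pose$N)^2)), 3)
  # the tail peak has the larger curvature
  ci <- prof$C[round(cands[[1]]$nose)]
  ct <- prof$C[round(cands[[1]]$tail)]
  expect_gt(ct, ci)

  # a disk has no supra-threshold maxima
  mask2 <- matrix(FALSE, 200, 200)
  xy <- expand.grid(x = 1:200, y = 1:200)
  inside <- (xy$x - 100)^2 + (xy$y - 100)^2 <= 30^2
  mask2[cbind(xy$y[inside], xy$x[inside])] <- TRUE
  cur2 <- extract_boundary(mask2, 1, 10)[[1]]
  expect_length(find_nose_tail(compute_curvature(cur2, 8), 0.08, 40), 0L)
})

test_that("two fish overlapping at the tails still yield two noses", {
  cfg <- sim_config(n_fish = 1, arena = c(600L, 600L), n_frames = 1, seed = 1)
  # antiparallel fish whose tails cross: a's tail extends towards +x,
  # b's towards -x, with a small lateral offset
  a <- synthetic_fish(c(240, 300), rep(pi, 8), cfg)
  b <- synthetic_fish(c(360, 318), rep(0, 8), cfg)
  mask <- a$mask | b$mask
  expect_gt(sum(a$mask & b$mask), 0)  # genuinely overlapping
  cur <- extract_boundary(mask, 1, 100)[[1]]
  prof <- compute_curvature(cur, 8)
  cands <- find_nose_tail(prof, 0.08, 40, curve = cur)
  noses <- t(vapply(cands, function(cc) fishchain:::boundary_at(cur$B, cc$nose),
                    numeric(2)))
  da <- min(sqrt(rowSums((noses - matrix(a$pose$N, nrow(noses), 2,
                                         byrow = TRUE))^2)))
  db <- min(sqrt(rowSums((noses - matrix(b$pose$N, nrow(noses), 2,
                                         byrow = TRUE))^2)))
  expect_lt(da, 5)
  expect_lt(db, 5)
})

test_that("head placement recovers position and orientation", {
  ff <- fish_frame(rep(0, 8), J1 = c(200, 256))
  mask <- segment_foreground(ff$img, ff$bg, 80)
  cur <- extract_boundary(mask, 1, 100)[[1]]
  prof <- compute_curvature(cur, 8)
  cands <- find_nose_tail(prof, 0.08, 40, curve = cur)
  ho <- head_from_nose(cur, cands[[1]]$nose, rect_spec(), ff$img,
                       neighbor_arc = 8, nose_margin = 10)
  expect_lt(abs(wrap_angle(ho$theta1 - 0)) * 180 / pi, 3)
  # J1 sits len_1 - nose_margin = 40 px behind the nose
  expect_lt(sqrt(sum((ho$J1 - (ho$N - 40 * c(cos(ho$theta1),
                                             -sin(ho$theta1))))^2)), 0.5)
  expect_equal(dim(ho$patch), c(35L, 50L))

  # reflection equivariance: mirror the frame about the vertical axis
  img_m <- ff$img[, ncol(ff$img):1]
  bg_m <- ff$bg
  det_m <- detect_frame(img_m, bg_m, fishchain_config())
  expect_length(det_m, 1L)
  expect_lt(abs(wrap_angle(det_m[[1]]$head$theta1 - pi)) * 180 / pi, 3)
})

test_that("chain fitting recovers straight and S-curved rectangle bodies", {
  spec <- rect_spec()
  set.seed(42)
  for (kind in c("straight", "scurve")) {
    h0 <- runif(1, -pi, pi)
    theta <- if (kind == "straight") rep(h0, 8) else s_curve_theta(h0)
    pose <- fish_pose(c(300, 300), theta, spec)
    mask <- render_pose(pose, spec, c(600, 600))
    set.seed(11)
    fit <- fit_chain_detection(c(300, 300), theta[1], spec, mask, n_pb = 256)
    expect_gte(fit$cover_ratio, 0.9)
    expect_true(attr(fit, "valid"))
    seg_err <- abs(wrap_angle(fit$theta[-1] - theta[-1])) * 180 / pi
    expect_lt(max(seg_err), 10)
    if (kind == "scurve") {
      jerr <- sqrt(rowSums((fit$J - pose$J)^2))
      expect_lt(max(jerr), 5)
    }
  }
  # an empty region is an invalid pose
  fit0 <- fit_chain_detection(c(10, 10), 0, spec,
                              matrix(numeric(0), ncol = 2), 32)
  expect_false(attr(fit0, "valid"))
  expect_equal(fit0$cover_ratio, 0)
})

test_that("frame detection finds well-separated fish and nothing on blanks", {
  params <- fishchain_config()
  blank <- matrix(200, 256, 256)
  expect_length(detect_frame(blank, blank, params), 0L)

  cfg <- sim_config(n_fish = 3, arena = c(1400L, 1400L), n_frames = 1, seed = 5)
  sim <- simulate_fish(cfg)
  img <- sim_frame(sim, 1)
  dets <- detect_frame(img, sim_background(sim), params)
  expect_length(dets, 3L)
  gt <- sim$truth[sim$truth$frame == 1, ]
  for (d in dets) {
    nerr <- min(sqrt((gt$nose_x - d$head$N[1])^2 + (gt$nose_y - d$head$N[2])^2))
    expect_lt(nerr, 3)
    expect_gte(d$pose$cover_ratio, 0.8)
  }
})

test_that("detection is equivariant under translation", {
  ff <- fish_frame(s_curve_theta(-0.6), J1 = c(200, 200))
  params <- fishchain_config()
  d0 <- detect_frame(ff$img, ff$bg, params)
  # translate the scene by (60, 40)
  img2 <- matrix(200, 512, 512)
  img2[41:512, 61:512] <- ff$img[1:472, 1:452]
  d1 <- detect_frame(img2, ff$bg, params)
  expect_length(d1, length(d0))
  expect_equal(d1[[1]]$head$N, d0[[1]]$head$N + c(60, 40), tolerance = 1.5)
})
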