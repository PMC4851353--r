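test_that("Kalman prediction realizes the constant-velocity recursion", {
  km <- kalman_model()
  pr <- kalman_predict(c(10, 20, 0.5, 8, 19, 0.4), diag(6) * 0, km)
  expect_equal(pr$X[1:3], c(12, 21, 0.6))
  # stationary fixed point
  pr2 <- kalman_predict(c(3, 4, 1, 3, 4, 1), diag(6), km)
  expect_equal(pr2$X[1:3], c(3, 4, 1))
  # covariance propagation with zero prior covariance
  km_q <- kalman_model(q = c(2, 2, 2))
  pr3 <- kalman_predict(rep(0, 6), matrix(0, 6, 6), km_q)
  expect_equal(pr3$P, diag(rep(2, 6)))
})

test_that("Kalman update limits behave as the closed form dictates", {
  km0 <- kalman_model(q = c(0, 0, 0), r = c(0, 0, 0))
  # R -> 0: posterior observed components equal the measurement
  up <- kalman_update(c(1, 2, 0.1, 0, 0, 0), diag(6), km0, c(9, 8, 0.7))
  expect_equal(up$X[1:3], c(9, 8, 0.7))
  # prior covariance zero: measurement ignored
  km <- kalman_model()
  up2 <- kalman_update(c(1, 2, 0.1, 0, 0, 0), matrix(0, 6, 6), km,
                       c(9, 8, 0.7))
  expect_equal(up2$X, c(1, 2, 0.1, 0, 0, 0))
  # scalar analogue: prior covariance I, R = I gives gain 1/2 on the
  # observed block
  km1 <- kalman_model(r = c(1, 1, 1))
  up3 <- kalman_update(rep(0, 6), diag(6), km1, c(2, 2, 0.2))
  expect_equal(up3$X[1:3], c(1, 1, 0.1))
})

test_that("angle innovations and coasting wrap correctly", {
  km <- kalman_model()
  tr <- list(X = c(12, 5, 0.1, 10, 5, 2 * pi - 0.1), P = km$P0, lost = 0L,
             frames = 1L, observed = TRUE,
             states = matrix(c(12, 5, 0.1), 1), poses = list(NULL))
  tr2 <- coast(tr, km, 2L)
  expect_equal(tr2$X[1], 14)
  expect_equal(tr2$X[3], 0.3, tolerance = 1e-12)
  expect_equal(tr2$lost, 1L)
})

test_that("normalized cross-correlation has its documented fixed points", {
  a <- matrix(runif(100, 1, 2), 10)
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a, 3 * a), 1)
  expect_equal(ncc(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 0)
  expect_equal(ncc(matrix(0, 4, 4), a[1:4, 1:4]), 0)
  # unequal sizes are resampled rather than erroring
  expect_no_error(ncc(a, a[1:5, 1:5]))
})

test_that("the von Mises density matches an independent Bessel-series oracle", {
  # modified Bessel function of order zero by its power series
  i0 <- function(x) sum(vapply(0:40, function(m) (x / 2)^(2 * m) /
                                 factorial(m)^2, 0))
  expect_equal(von_mises_density(0.3, 0.3, 4), exp(4) / (2 * pi * i0(4)),
               tolerance = 1e-6)
  expect_equal(von_mises_density(pi + 0.2, 0.2, 4),
               exp(-4) / (2 * pi * i0(4)), tolerance = 1e-9)
  # density normalization for several concentrations
  for (k in c(0.5, 2, 4)) {
    ys <- seq(0, 2 * pi, length.out = 20001)[-20001]
    expect_equal(mean(von_mises_density(ys, 1, k)) * 2 * pi, 1,
                 tolerance = 1e-6)
  }
})

test_that("the von Mises sampler concentrates around its mean", {
  set.seed(5)
  x <- rvon_mises(4000, 0.8, 4)
  expect_lt(abs(atan2(mean(sin(x)), mean(cos(x))) - 0.8), 0.05)
  # resultant length of vM(k=4) is I1(k)/I0(k) ~ 0.863
  expect_equal(sqrt(mean(sin(x))^2 + mean(cos(x))^2), 0.863,
               tolerance = 0.03)
  u <- rvon_mises(4000, 0, 0)
  expect_lt(sqrt(mean(sin(u))^2 + mean(cos(u))^2), 0.05)
})

test_that("association cost combines appearance and orientation with gates", {
  p <- matrix(runif(100, 10, 200), 10)
  expect_equal(association_cost(p, 0.5, p, 0.5, k = 4),
               exp(-(1 + von_mises_density(0, 0, 4))), tolerance = 1e-9)
  # NCC gate
  expect_equal(association_cost(matrix(c(1, 0), 1), 0, matrix(c(0, 1), 1), 0),
               Inf)
  # orientation gate: opposite headings
  expect_equal(association_cost(p, 0, p, pi), Inf)
  # strictly decreasing in orientation agreement
  c1 <- association_cost(p, 0, p, 0.1)
  c2 <- association_cost(p, 0, p, 0.5)
  expect_lt(c1, c2)
})

test_that("Kuhn-Munkres matches brute force on seeded matrices", {
  expect_equal(associate(matrix(c(1, 2, 2, 1), 2))$pairs,
               matrix(c(1L, 2L, 1L, 2L), 2, dimnames = list(NULL, c("row", "col"))))
  a1 <- associate(matrix(Inf, 1, 1))
  expect_equal(nrow(a1$pairs), 0L)
  expect_equal(a1$unassigned_rows, 1L)
  expect_equal(a1$unassigned_cols, 1L)
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(1:5, 1)
    m <- sample(1:5, 1)
    C <- matrix(runif(n * m, 0, 10), n, m)
    C[runif(n * m) < 0.2] <- Inf
    res <- associate(C)
    bf <- brute_force_assignment(C)
    expect_equal(nrow(res$pairs), bf$n_assigned)
    expect_equal(res$total_cost, bf$total_cost, tolerance = 1e-9)
  }
  # permutation equivariance in the measurements
  set.seed(3)
  C <- matrix(runif(12, 1, 5), 3, 4)
  perm <- c(3, 1, 4, 2)
  r1 <- associate(C)
  r2 <- associate(C[, perm])
  m1 <- r1$pairs[order(r1$pairs[, 1]), , drop = FALSE]
  m2 <- r2$pairs[order(r2$pairs[, 1]), , drop = FALSE]
  expect_equal(perm[m2[, 2]], m1[, 2])
})

test_that("body tracking refits a translated fish and vetoes bad heads", {
  spec <- rect_spec()
  theta <- s_curve_theta(0.4)
  u <- c(cos(0.4), -sin(0.4))
  prev <- fish_pose(c(280, 300), theta, spec, nose_margin = 10)
  moved <- fish_pose(c(280, 300) + 5 * u, theta, spec, nose_margin = 10)
  region <- render_pose(moved, spec, c(600, 600))
  set.seed(8)
  fit <- track_body(moved$J[1, ], theta[1], region, prev, spec,
                    n_pb = 256, k_body = 4, nose_margin = 10)
  expect_true(attr(fit, "valid"))
  expect_lt(max(sqrt(rowSums((fit$J - moved$J)^2))), 3)
  # straight previous pose, straight region: angles within 5 degrees
  prev_s <- fish_pose(c(280, 300), rep(0.4, 8), spec, nose_margin = 10)
  region_s <- render_pose(prev_s, spec, c(600, 600))
  set.seed(9)
  fit_s <- track_body(prev_s$J[1, ], 0.4, region_s, prev_s, spec,
                      n_pb = 256, k_body = 4, nose_margin = 10)
  expect_lt(max(abs(wrap_angle(fit_s$theta - 0.4))) * 180 / pi, 5)
  # a head joint on background is vetoed
  set.seed(10)
  bad <- track_body(c(50, 50), 0.4, region_s, prev_s, spec, n_pb = 64,
                    nose_margin = 10)
  expect_false(attr(bad, "valid"))
})

test_that("tracker lifecycle follows the association outcomes", {
  params <- fishchain_config()
  km <- kalman_model(params$kalman_q, params$kalman_r, params$kalman_p0)
  cfg <- sim_config(n_fish = 1, arena = c(700L, 700L), n_frames = 1, seed = 1)
  # craft three well-separated static fish and their detections
  make_det <- function(J1, th, labmat, label, frame_img) {
    sf <- synthetic_fish(J1, rep(th, 8), cfg)
    pose <- fish_pose(J1, rep(th, 8), rect_spec(), nose_margin = 10,
                      cover_ratio = 0.95)
    u <- c(cos(th), -sin(th))
    G <- J1 + 50 * u
    patch <- fishchain:::sample_head_patch(frame_img, G, th, 50, 35)
    list(pose = pose, head = list(N = J1 + 40 * u, theta1 = th, J1 = J1,
                                  G = G, patch = patch), label = label)
  }
  Js <- list(c(150, 150), c(450, 150), c(300, 500))
  ths <- c(0, 1, -2)
  img <- matrix(200, 700, 700)
  masks <- list()
  for (i in 1:3) {
    sf <- synthetic_fish(Js[[i]], rep(ths[i], 8), cfg)
    img[sf$mask] <- 40
    masks[[i]] <- sf$mask
  }
  labmat <- matrix(0L, 700, 700)
  for (i in 1:3) labmat[masks[[i]]] <- i
  dets <- lapply(1:3, function(i) make_det(Js[[i]], ths[i], labmat, i, img))

  set.seed(21)
  st <- step_frame(list(), dets, labmat, 1L, params, km, 1L)
  expect_length(st$trackers, 3L)
  st2 <- step_frame(st$trackers, dets, labmat, 2L, params, km, st$next_id)
  expect_length(st2$trackers, 3L)
  expect_length(st2$finished, 0L)
  expect_equal(st2$next_id, st$next_id)   # no spawns on clean association

  # a tracker that stays unassociated coasts and dies after 5 extra frames
  trackers <- st2$trackers[1]
  for (f in 3:7) {
    sf <- step_frame(trackers, list(), labmat, f, params, km, 10L)
    trackers <- sf$trackers
    expect_length(sf$finished, 0L)
  }
  sf <- step_frame(trackers, list(), labmat, 8L, params, km, 10L)
  expect_length(sf$trackers, 0L)
  expect_length(sf$finished, 1L)
  expect_equal(sf$finished[[1]]$reason, "lost")

  # a one-frame tracker that loses its target is discarded entirely
  st1 <- step_frame(list(), dets[1], labmat, 1L, params, km, 1L)
  gone <- step_frame(st1$trackers, list(), labmat, 2L, params, km, 2L)
  expect_length(gone$trackers, 0L)
  expect_length(gone$finished, 0L)
})

test_that("noise-free Kalman tracking of a constant-velocity head is exact", {
  params <- fishchain_config(kalman_q = c(0, 0, 0), kalman_r = c(0, 0, 0))
  km <- kalman_model(c(0, 0, 0), c(0, 0, 0))
  v <- c(3, 2)
  J <- c(100, 100)
  X <- NULL
  P <- NULL
  for (f in 1:6) {
    Z <- c(J + f * v, 0.3)
    if (f == 1) {
      X <- c(Z, Z)
      P <- km$P0
    } else {
      pr <- kalman_predict(X, P, km)
      if (f >= 3) expect_equal(pr$X[1:2], J + f * v, tolerance = 1e-12)
      up <- kalman_update(pr$X, pr$P, km, Z)
      X <- up$X
      P <- up$P
    }
    expect_equal(X[1:2], J + f * v, tolerance = 1e-12)
  }
})
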