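# Shared fixtures: controlled poses, rendered frames and brute-force
# oracles, all generated in code.

# A straight default-spec pose anchored on half-integer coordinates so
# that rasterized pixel counts are exact.
straight_pose <- function(x = 300.5, y = 300.5, theta = pi, spec = rect_spec()) {
  # theta = pi: the chain extends towards +x from the front edge at (x, y)
  fish_pose(c(x, y) - spec$lengths[1] * c(cos(theta), -sin(theta)),
            rep(theta, spec$n_r), spec)
}

# Alternating +/-30 degree S-curve bends appended to heading h0.
s_curve_theta <- function(h0, n_r = 8L) {
  h0 + c(0, rep(c(30, -30), length.out = n_r - 1L) * pi / 180)
}

# Render a single smooth synthetic fish on a plate, with sensor noise.
fish_frame <- function(theta, J1 = c(256, 256), arena = c(512L, 512L),
                       noise_seed = 1L, cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- sim_config(n_fish = 1, arena = arena, n_frames = 1, seed = 1,
                      wall_margin = 100)
  }
  sf <- synthetic_fish(J1, theta, cfg)
  img <- matrix(cfg$plate, arena[1], arena[2])
  img[sf$mask] <- cfg$fish_gray
  set.seed(noise_seed)
  img <- img + matrix(rnorm(length(img), 0, cfg$noise_sd), arena[1])
  list(img = pmin(pmax(img, 0), 255), bg = matrix(cfg$plate, arena[1], arena[2]),
       pose = sf$pose, mask = sf$mask, cfg = cfg)
}

# Brute-force minimum-cost assignment by permutation enumeration; Inf
# entries forbid a pairing, and the assignment maximizing the number of
# realized (finite) pairings with minimal total cost is returned.
brute_force_assignment <- function(C) {
  n <- nrow(C)
  m <- ncol(C)
  k <- max(n, m)
  Cs <- matrix(Inf, k, k)
  Cs[seq_len(n), seq_len(m)] <- C
  perms <- all_permutations(k)
  best_cost <- Inf
  best_n <- -1L
  for (p in perms) {
    costs <- Cs[cbind(seq_len(k), p)]
    realized <- is.finite(costs)
    total <- sum(costs[realized])
    if (sum(realized) > best_n ||
        (sum(realized) == best_n && total < best_cost)) {
      best_n <- sum(realized)
      best_cost <- total
    }
  }
  list(total_cost = best_cost, n_assigned = best_n)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force minimum cost of choosing exactly k link edges forming
# vertex-disjoint chains (each tracklet at most one successor and one
# predecessor). Returns Inf when infeasible.
brute_force_links <- function(edges, k) {
  if (k == 0L) return(0)
  ne <- nrow(edges)
  if (ne < k) return(Inf)
  best <- Inf
  combos <- utils::combn(ne, k)
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    if (anyDuplicated(edges$i[sel]) || anyDuplicated(edges$j[sel])) next
    best <- min(best, sum(edges$cost[sel]))
  }
  best
}

# Minimal synthetic tracklet object for relinking tests.
fake_tracklet <- function(id, st, ed, p_in, th_in, p_out, th_out) {
  structure(list(id = id, st = st, ed = ed,
                 head_in = c(p_in, th_in), head_out = c(p_out, th_out),
                 poses = list(), n_obs = ed - st + 1L, reason = "end"),
            class = "tracklet")
}

# Random gated tracklet set whose link graph has a controlled number of
# candidate edges.
random_tracklets <- function(n, seed) {
  set.seed(seed)
  tks <- list()
  t0 <- 1
  for (i in seq_len(n)) {
    st <- t0 + sample(0:3, 1)
    ed <- st + sample(5:20, 1)
    p1 <- runif(2, 100, 400)
    p2 <- p1 + runif(2, -40, 40)
    tks[[i]] <- fake_tracklet(i, st, ed, p1, runif(1, -pi, pi),
                              p2, runif(1, -pi, pi))
    t0 <- st + sample(2:8, 1)
  }
  tks
}
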