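test_that("link graph edges respect the three gates", {
  a <- fake_tracklet(1, 1, 100, c(0, 0), 0, c(500, 500), 0.2)
  gap3 <- fake_tracklet(2, 103, 150, c(530, 520), 0.3, c(700, 700), 0.3)
  gap7 <- fake_tracklet(3, 107, 150, c(530, 520), 0.3, c(700, 700), 0.3)
  far <- fake_tracklet(4, 103, 150, c(600, 500), 0.3, c(700, 700), 0.3)

  g1 <- build_link_graph(list(a, gap3))
  expect_equal(nrow(g1$edges), 1L)
  expect_equal(g1$edges$gap, 3)
  expect_equal(g1$edges$cost,
               exp(g1$edges$D) * exp(-von_mises_density(0.3, 0.2, 4)),
               tolerance = 1e-9)
  # a 7-frame gap is not less than max_interf = 6
  expect_equal(nrow(build_link_graph(list(a, gap7))$edges), 0L)
  # distance 100 exceeds max_interd = 80
  expect_equal(nrow(build_link_graph(list(a, far))$edges), 0L)
  # links never go backward or same-frame
  g2 <- build_link_graph(list(gap3, a))
  expect_true(all(g2$edges$gap > 0))
})

test_that("min-cost flow picks the cheapest feasible link set", {
  a <- fake_tracklet(1, 1, 100, c(0, 0), 0, c(500, 500), 0)
  b <- fake_tracklet(2, 103, 150, c(502, 500), 0, c(700, 700), 0)
  g <- build_link_graph(list(a, b))
  sol <- solve_mcmf(g, 1)
  expect_true(sol$feasible)
  expect_equal(nrow(sol$links), 1L)

  # two successors at different costs: the cheaper one wins
  c2 <- fake_tracklet(3, 103, 150, c(530, 500), 0, c(900, 900), 0)
  g3 <- build_link_graph(list(a, b, c2))
  sol3 <- solve_mcmf(g3, 2)   # 3 tracklets, 1 link
  expect_true(sol3$feasible)
  expect_equal(sol3$links$j, 2L)  # the nearer (cheaper) successor
  # infeasible demanded flow
  expect_false(solve_mcmf(g3, 1)$feasible)
})

test_that("flow solutions match brute force on seeded gated graphs", {
  checked <- 0L
  for (s in 1:25) {
    tks <- random_tracklets(sample(4:8, 1), seed = 1000 + s)
    g <- build_link_graph(tks)
    if (nrow(g$edges) == 0L) next
    max_k <- min(nrow(g$edges), g$n - 1L)
    for (k in 0:max_k) {
      bf <- brute_force_links(g$edges, k)
      sol <- solve_mcmf(g, g$n - k)
      if (is.infinite(bf)) {
        expect_false(sol$feasible)
      } else {
        expect_true(sol$feasible)
        expect_equal(sol$total_cost, bf, tolerance = 1e-6)
        # unit capacities: disjoint chains
        expect_equal(anyDuplicated(sol$links$i), 0L)
        expect_equal(anyDuplicated(sol$links$j), 0L)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 20L)
})

test_that("relinking restores an artificially cut trajectory", {
  cfg <- sim_config(n_fish = 1, arena = c(700L, 700L), n_frames = 80, seed = 3)
  sim <- simulate_fish(cfg)
  params <- fishchain_config()
  tk <- track_sequence(sim_frames(sim), sim_background(sim), params, seed = 1)
  expect_length(tk, 1L)
  # cut the tracklet at frame 40 with a 2-frame gap
  whole <- tk[[1]]
  cut_at <- 40L
  first <- whole
  keep1 <- whole$frames <= cut_at
  first$frames <- whole$frames[keep1]
  first$observed <- whole$observed[keep1]
  first$states <- whole$states[keep1, , drop = FALSE]
  first$ed <- cut_at
  first$head_out <- first$states[nrow(first$states), ]
  first$poses <- whole$poses[vapply(whole$poses, function(p)
    p$frame <= cut_at, logical(1))]
  second <- whole
  second$id <- 2L
  keep2 <- whole$frames >= cut_at + 3L
  second$frames <- whole$frames[keep2]
  second$observed <- whole$observed[keep2]
  second$states <- whole$states[keep2, , drop = FALSE]
  second$st <- cut_at + 3L
  second$head_in <- second$states[1, ]
  second$poses <- whole$poses[vapply(whole$poses, function(p)
    p$frame >= cut_at + 3L, logical(1))]
  rl <- relink(list(first, second), params)
  expect_equal(nrow(rl$links), 1L)
  traj <- trajectories_table(rl, params$spec)
  expect_length(unique(traj$id), 1L)
  expect_equal(unique(traj$id), first$id)

  # with no candidate edges the input passes through unchanged
  lone <- fake_tracklet(5, 1, 10, c(0, 0), 0, c(40, 40), 0)
  rl0 <- relink(list(lone), params)
  expect_equal(nrow(rl0$links), 0L)
  expect_equal(rl0$tracklets[[1]]$id, 5)
})
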