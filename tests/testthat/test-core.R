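test_that("uniform initialisation fills the box at the nominal density", {
  set.seed(1)
  st <- init_uniform(swarm_params())
  expect_equal(nrow(st$positions), 91L)
  expect_true(all(st$positions >= 0 & st$positions <= 1.74))
  expect_equal(st$t, 0L)

  st1 <- init_uniform(swarm_params(P = 1L))
  expect_equal(nrow(st1$positions), 1L)

  # law of large numbers on the sampler: mean x within 3 sigma of L/2
  set.seed(42)
  big <- init_uniform(swarm_params(P = 1000L, L = 1))
  sigma <- 1 / sqrt(12 * 1000)
  expect_lt(abs(mean(big$positions[, 1]) - 0.5), 3 * sigma)
})

test_that("gaze sampling is uniform on [0, 2*pi) and reproducible", {
  set.seed(6)
  g <- sample_gaze(1e5)
  expect_true(all(g >= 0 & g < 2 * pi))
  ks <- suppressWarnings(stats::ks.test(g, "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
  set.seed(6)
  expect_identical(sample_gaze(1e5), g)
})

test_that("sector search matches the geometry and the brute-force oracle", {
  pos <- rbind(c(0, 0), c(1, 0), c(0.1, 0.9))
  expect_equal(sector_nearest_neighbour(pos, 1, gaze = 0, alpha = pi / 2), 2L)
  # full field: plain nearest neighbour (Hamilton's rule)
  pos2 <- rbind(c(0, 0), c(1, 0), c(0, 0.5))
  expect_equal(sector_nearest_neighbour(pos2, 1, gaze = 0, alpha = 2 * pi), 3L)
  # empty sector is a valid outcome
  expect_true(is.na(sector_nearest_neighbour(pos2, 1, gaze = pi, alpha = pi / 4)))
  # closed sector boundary: bearing exactly at +alpha/2 is inside
  pos3 <- rbind(c(0, 0), c(1, 1))  # bearing atan2(1, 1) = alpha/2 exactly
  expect_equal(sector_nearest_neighbour(pos3, 1, gaze = 0, alpha = pi / 2), 2L)

  set.seed(11)
  for (trial in 1:300) {
    pts <- cbind(runif(50), runif(50))
    i <- sample(50, 1)
    gaze <- runif(1, 0, 2 * pi)
    alpha <- sample(c(runif(1, 0.05, 2 * pi), 2 * pi), 1)
    got <- sector_nearest_neighbour(pts, i, gaze, alpha)
    want <- brute_sector_nn(pts, i, gaze, alpha)
    expect_identical(got, want)
  }
})

test_that("movement rule: attraction step, stress-zone and ideal-distance stops", {
  p <- swarm_params(P = 2L, L = 10, D = 0.1, v = 0.3)
  st <- swarm_state(rbind(c(5, 5), c(6, 5)))
  out <- move_agent(st, 1, 2, p)
  expect_equal(out$state$positions[1, ], c(5.3, 5))
  expect_true(out$moved)
  expect_equal(out$displacement_norm, 0.3)

  # would invade the stress zone: stop exactly at D from the neighbour
  p2 <- swarm_params(P = 2L, L = 10, D = 0.1, v = 0.1)
  st2 <- swarm_state(rbind(c(5, 5), c(5.15, 5)))
  out2 <- move_agent(st2, 1, 2, p2)
  expect_equal(out2$state$positions[1, ], c(5.05, 5))
  expect_equal(sqrt(sum((out2$state$positions[1, ] - c(5.15, 5))^2)), 0.1)

  # repulsion overshoot: stop exactly at D on the far side
  p3 <- swarm_params(P = 2L, L = 10, D = 0.1, v = 0.2)
  st3 <- swarm_state(rbind(c(5, 5), c(5.05, 5)))
  out3 <- move_agent(st3, 1, 2, p3)
  expect_equal(out3$state$positions[1, ], c(4.95, 5))

  # at the ideal distance: no movement at all
  st4 <- swarm_state(rbind(c(5, 5), c(5.1, 5)))
  out4 <- move_agent(st4, 1, 2, p3)
  expect_false(out4$moved)
  expect_equal(out4$displacement_norm, 0)

  expect_error(move_agent(st4, 2, 2, p3), "differ")
})

test_that("updates never exceed the step length and respect the D-clamps", {
  p <- swarm_params(P = 10L, L = 1, D = 0.1, v = 0.07)
  for (eta in c(0, 0.3, 1)) {
    p$eta <- eta
    set.seed(100 + round(10 * eta))
    for (k in 1:200) {
      pos <- cbind(runif(10, 0.2, 0.8), runif(10, 0.2, 0.8))
      ij <- sample(10, 2)
      d0 <- sqrt(sum((pos[ij[1], ] - pos[ij[2], ]) ^ 2))
      out <- move_agent(swarm_state(pos), ij[1], ij[2], p)
      d1 <- sqrt(sum((out$state$positions[ij[1], ] - pos[ij[2], ]) ^ 2))
      expect_lte(out$displacement_norm, p$v + 1e-12)
      if (d0 > p$D + 1e-9) expect_gte(d1, p$D - 1e-9)
      if (d0 < p$D - 1e-9) expect_lte(d1, p$D + 1e-9)
    }
  }
})

test_that("a perfect lattice is a fixed point for alpha >= pi/3, not below", {
  lat <- make_triangular_lattice(0.1, shells = 2, center = c(1, 1))
  for (alpha in c(pi / 3, pi / 2, pi, 2 * pi)) {
    p <- swarm_params(P = nrow(lat$positions), L = 2, D = 0.1, v = 0.0112,
                      alpha = alpha)
    st <- swarm_state(lat$positions)
    set.seed(3)
    for (s in 1:20) {
      sw <- sweep_agents(st, p)
      st <- sw$state
      expect_equal(sw$moved, 0L)
    }
    expect_equal(st$positions, lat$positions)
  }
  # below pi/3 a gaze bisecting two first-shell bearings sees only the
  # second shell at sqrt(3)*D, which triggers an attraction move
  centre <- which(colSums(abs(t(lat$positions) - c(1, 1))) < 1e-12)
  j <- sector_nearest_neighbour(lat$positions, centre, gaze = pi / 6,
                                alpha = pi / 6)
  expect_false(is.na(j))
  dj <- sqrt(sum((lat$positions[j, ] - c(1, 1))^2))
  expect_equal(dj, sqrt(3) * 0.1, tolerance = 1e-12)
  p_small <- swarm_params(P = nrow(lat$positions), L = 2, D = 0.1,
                          v = 0.0112, alpha = pi / 6)
  out <- move_agent(swarm_state(lat$positions), centre, j, p_small)
  expect_true(out$moved)
})

test_that("two isolated agents settle at separation exactly D", {
  # from above: approach in v-steps, then clamp onto the D-circle
  p <- swarm_params(P = 2L, L = 10, D = 0.1, v = 0.05, alpha = 2 * pi)
  st <- swarm_state(rbind(c(5, 5), c(5 + 0.1 + 3 * 0.05, 5)))
  set.seed(8)
  for (k in 1:20) st <- sweep_agents(st, p)$state
  expect_lt(abs(dist(st$positions) - 0.1), 1e-12)

  # from below: single repulsion overshoot lands on the circle
  st2 <- swarm_state(rbind(c(5, 5), c(5.03, 5)))
  set.seed(9)
  for (k in 1:10) st2 <- sweep_agents(st2, p)$state
  expect_lt(abs(dist(st2$positions) - 0.1), 1e-12)
})

test_that("agents stay inside the box under violent noisy dynamics", {
  p <- swarm_params(P = 15L, L = 0.5, D = 0.1, v = 0.3, alpha = 2 * pi,
                    eta = 1, seed = 21L)
  set.seed(p$seed)
  st <- init_uniform(p)
  for (k in 1:50) {
    sw <- sweep_agents(st, p)
    st <- sw$state
    expect_true(all(st$positions >= 0 & st$positions <= p$L))
    expect_gte(sw$moved, 0L)
    expect_lte(sw$moved, p$P)
  }
})

test_that("trajectories are bit-for-bit reproducible under a fixed seed", {
  p <- swarm_params(P = 20L, L = 0.81, alpha = 2.5, eta = 0.2, seed = 77L,
                    max_sweeps = 300L)
  tr1 <- run_swarm(p, sample_every = 50L)
  tr2 <- run_swarm(p, sample_every = 50L)
  expect_identical(tr1$samples, tr2$samples)
  expect_identical(tr1$t_conv, tr2$t_conv)
  expect_identical(tr1$moved_counts, tr2$moved_counts)

  p$seed <- 78L
  tr3 <- run_swarm(p, sample_every = 50L)
  expect_false(identical(tr1$samples, tr3$samples))
})

test_that("run handles quiescent starts and the sweep cap", {
  lat <- make_triangular_lattice(0.1, shells = 2, center = c(1, 1))
  p <- swarm_params(P = nrow(lat$positions), L = 2, alpha = pi / 2,
                    qs_window = 50L, max_sweeps = 1000L, seed = 4L)
  tr <- run_swarm(p, init = swarm_state(lat$positions), sample_every = 1000L)
  expect_true(tr$converged)
  expect_equal(tr$t_conv, 0L)

  p2 <- swarm_params(P = 10L, L = 0.5, max_sweeps = 1L, seed = 5L)
  tr2 <- run_swarm(p2, sample_every = 10L)
  expect_false(tr2$converged)
  expect_true(is.na(tr2$t_conv))
  expect_equal(length(tr2$samples), 2L)  # initial plus final
})

test_that("the absorbing-state detector accepts lattices and rejects noise", {
  lat <- make_triangular_lattice(0.05, shells = 3)
  expect_true(is_absorbing(lat$positions, D = 0.05))
  set.seed(2)
  expect_false(is_absorbing(cbind(runif(30), runif(30)), D = 0.05))
  pert <- lat$positions
  pert[5, ] <- pert[5, ] + c(10 * 1e-9, 0)
  expect_false(is_absorbing(pert, D = 0.05, tol = 1e-9))
})
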