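# Experiment-layer tests run on deliberately small systems (P of order 20
# at the standard density) so the whole file stays in tens of seconds.

dens_L <- function(P) sqrt(P / (91 / 1.74^2))  # box side at the standard density

test_that("replicate seeds are deterministic, in range, and value-keyed", {
  s1 <- swarmattn:::replicate_seed(1L, swarmattn:::param_key(0.5), 3L)
  s2 <- swarmattn:::replicate_seed(1L, swarmattn:::param_key(0.5), 3L)
  expect_identical(s1, s2)
  expect_true(s1 >= 1 && s1 <= 2^31 - 1)
  reps <- vapply(1:50, function(r)
    swarmattn:::replicate_seed(1L, swarmattn:::param_key(0.5), r), integer(1))
  expect_equal(length(unique(reps)), 50L)
  # different grid values decouple
  expect_false(swarmattn:::replicate_seed(1L, swarmattn:::param_key(0.6), 3L) == s1)
})

test_that("reordering the alpha grid leaves per-alpha results unchanged", {
  base <- swarm_params(P = 12L, L = dens_L(12), max_sweeps = 150L, seed = 1L)
  g1 <- c(pi / 2, pi)
  sw1 <- sweep_alpha(base, g1, replicates = 2L, seed0 = 9L)
  sw2 <- sweep_alpha(base, rev(g1), replicates = 2L, seed0 = 9L)
  for (a in g1) {
    r1 <- sw1$per_replicate[sw1$per_replicate$alpha == a, ]
    r2 <- sw2$per_replicate[sw2$per_replicate$alpha == a, ]
    rownames(r1) <- rownames(r2) <- NULL
    expect_equal(r1, r2)
  }
})

test_that("censored convergence accounting is exact", {
  base <- swarm_params(P = 12L, L = dens_L(12), max_sweeps = 100L, seed = 2L)
  sw <- sweep_alpha(base, c(pi / 2, 2 * pi), replicates = 4L, seed0 = 5L)
  expect_equal(sw$summary$convergence_prob * sw$summary$replicates,
               sw$summary$n_converged)
  expect_equal(sw$summary$n_converged + sw$summary$n_censored,
               sw$summary$replicates)
  # per-replicate flags are preserved, never silently dropped
  expect_equal(sum(sw$per_replicate$converged),
               sum(sw$summary$n_converged))
  # the fluctuation-peak locations are members of the grid
  expect_true(sw$peaks$psi6 %in% sw$grid && sw$peaks$T %in% sw$grid)
})

test_that("the power-law fit recovers a known exponent", {
  set.seed(900)
  P <- c(20, 40, 80, 160, 320)
  for (k in 1:5) {
    gamma <- runif(1, 0.5, 2)
    t <- 3 * P^gamma * exp(rnorm(length(P), 0, 0.05))
    fit <- swarmattn:::power_fit(P, t)
    expect_lt(abs(fit$gamma - gamma), 2 * fit$se + 1e-8)
  }
})

test_that("an interior speed optimum minimises the convergence time", {
  base <- swarm_params(P = 19L, L = dens_L(19), alpha = 150 * pi / 180,
                       max_sweeps = 60000L, seed = 3L)
  sw <- sweep_speed(base, v_grid = c(0.005, 0.03, 0.08), replicates = 4L,
                    seed0 = 17L)
  s <- sw$summary
  expect_true(all(!is.na(s$t_conv_mean)))
  mid <- s$t_conv_mean[s$v == 0.03]
  expect_lt(mid, s$t_conv_mean[s$v == 0.005])
  expect_lt(mid, s$t_conv_mean[s$v == 0.08])
  expect_equal(sw$optimal$v_opt, 0.03)
  # identical seeds give identical convergence times
  sw2 <- sweep_speed(base, v_grid = 0.03, replicates = 4L, seed0 = 17L)
  expect_identical(sw2$per_replicate$t_conv,
                   sw$per_replicate$t_conv[sw$per_replicate$v == 0.03])
})

test_that("noise destroys sixfold order abruptly at a critical strength", {
  base <- swarm_params(P = 19L, L = dens_L(19), alpha = 150 * pi / 180,
                       seed = 4L)
  sw <- sweep_noise(base, eta_grid = c(0, 0.3, 0.6, 1), horizon = 3000L,
                    replicates = 3L, seed0 = 23L)
  s <- sw$summary
  expect_gt(s$psi6_mean[s$eta == 0], 0.6)
  expect_gt(s$psi6_mean[s$eta == 0.3], 0.6)
  expect_lt(s$psi6_mean[s$eta == 0.6], 0.35)
  # full noise is statistically indistinguishable from random points:
  # the n = 19 null level of |mean psi6| is well below 0.35
  expect_lt(s$psi6_mean[s$eta == 1], 0.35)
  expect_true(!is.na(sw$eta_c) && sw$eta_c > 0.2 && sw$eta_c < 0.8)
})

test_that("the herd scenario contracts the domain of danger", {
  h <- herd_scenario(swarm_params(P = 90L, alpha = pi / 2, eta = 0.1,
                                  seed = 42L),
                     horizon = 300L)
  expect_equal(h$A_norm[1], 1)
  expect_lt(h$A_norm[length(h$A_norm)], 0.6)
  expect_equal(h$reduction_horizon, 1 - h$A_norm[length(h$A_norm)])
  expect_equal(h$ts[1], 0L)
  expect_lte(max(h$ts), 300L)
})

test_that("the Hamilton limit fragments while a narrow field stays cohesive", {
  # paired smoke test of the selfish-herd contrast at reduced size
  base <- swarm_params(P = 30L, L = dens_L(30), max_sweeps = 20000L)
  frag <- base; frag$alpha <- 2 * pi; frag$seed <- 91L
  coh <- base; coh$alpha <- pi / 2; coh$seed <- 91L
  tr_f <- run_swarm(frag, sample_every = frag$max_sweeps)
  tr_c <- run_swarm(coh, sample_every = coh$max_sweeps)
  fin_f <- final_state(tr_f); fin_c <- final_state(tr_c)
  expect_gt(max(cluster_components(fin_f$positions, 1.5 * base$D)), 1L)
  expect_equal(max(cluster_components(fin_c$positions, 1.5 * base$D)), 1L)
  red_f <- area_reduction(tr_f$samples[[1]], fin_f$positions, D = base$D)
  red_c <- area_reduction(tr_c$samples[[1]], fin_c$positions, D = base$D)
  expect_gt(red_c, 0.5)
  expect_lt(red_f, red_c)
})
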