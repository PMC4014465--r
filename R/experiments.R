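# Scripted, seeded, replicate-averaged experiments.  Each experiment is a
# pure function of (base params, grids, replicates, seed0): replicate seeds
# are derived by hashing the grid *values* (not positions), so extending or
# reordering a grid never perturbs existing cells.

M31 <- 2147483647  # 2^31 - 1

# Deterministic seed stream: Lehmer-style mixing of seed0, integer keys and
# the replicate index.  Products stay below 2^53 so double arithmetic is
# exact.  Result in [1, 2^31 - 1].
replicate_seed <- function(seed0, keys, rep_index) {
  h <- as.numeric(seed0) %% M31
  for (k in c(as.numeric(keys) %% M31, as.numeric(rep_index))) {
    h <- (h * 48271 + k + 1) %% M31
    h <- (h * 48271) %% M31
  }
  as.integer(h + 1)
}

param_key <- function(x) round(as.numeric(x) * 1e9) %% M31

run_replicate <- function(params, r_T_factor, link_factor) {
  tr <- run_swarm(params, sample_every = params$max_sweeps)
  fin <- final_state(tr)
  met <- swarm_metrics(fin, params, r_T_factor = r_T_factor,
                       link_factor = link_factor)
  met$area_reduction <- area_reduction(tr$samples[[1]], fin$positions,
                                       D = params$D)
  met$t <- NULL
  cbind(data.frame(seed = params$seed, converged = tr$converged,
                   t_conv = tr$t_conv, sweeps_run = tr$sweeps_run,
                   clamp_events = tr$clamp_events), met)
}

summarise_cell <- function(df) {
  num <- c("psi6", "T", "mean_area", "total_area", "n_clusters",
           "area_reduction")
  out <- data.frame(replicates = nrow(df))
  for (v in num) {
    out[[paste0(v, "_mean")]] <- mean(df[[v]])
    out[[paste0(v, "_sd")]] <- if (nrow(df) > 1) sd(df[[v]]) else 0
  }
  out$n_converged <- sum(df$converged)
  out$convergence_prob <- mean(df$converged)
  out$t_conv_mean <- if (any(df$converged)) mean(df$t_conv[df$converged]) else NA_real_
  out$n_censored <- sum(!df$converged)
  out
}

#' Attention-angle sweep
#'
#' For every `alpha` in the grid runs `replicates` independent seeded
#' simulations to quasi-stationarity (or `max_sweeps`), evaluates the order
#' metrics and the domain-of-danger area reduction on the final state, and
#' aggregates means and standard deviations.  Non-converged replicates are
#' kept (with their final state) and flagged; the `alpha` of maximal
#' standard deviation of each order parameter — the fluctuation peak that
#' marks the order-disorder boundary — is reported.
#'
#' @param base A [swarm_params()]; everything but `alpha` and `seed` is
#'   taken from it.
#' @param alpha_grid Attention angles, radians in `(0, 2*pi]`.
#' @param replicates Independent runs per grid value (>= 1).
#' @param seed0 Master seed of the experiment.
#' @param r_T_factor,link_factor Metric conventions, see [swarm_metrics()].
#' @return An object of class `swarm_sweep`: `parameter`, `grid`,
#'   `per_replicate` (one row per run), `summary` (one row per grid value),
#'   `peaks` (fluctuation-peak locations), `seed0`.
#' @export
sweep_alpha <- function(base, alpha_grid, replicates = 100L,
                        seed0 = base$seed, r_T_factor = 1.3,
                        link_factor = 1.5) {
  validate_params(base)
  stopifnot(replicates >= 1, all(alpha_grid > 0 & alpha_grid <= 2 * pi))
  per <- do.call(rbind, lapply(seq_along(alpha_grid), function(g) {
    a <- alpha_grid[g]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      p <- base
      p$alpha <- a
      p$seed <- replicate_seed(seed0, param_key(a), r)
      cbind(data.frame(alpha = a, rep = r),
            run_replicate(p, r_T_factor, link_factor))
    }))
  }))
  summ <- do.call(rbind, lapply(alpha_grid, function(a)
    cbind(data.frame(alpha = a), summarise_cell(per[per$alpha == a, ]))))
  peaks <- list(psi6 = summ$alpha[which.max(summ$psi6_sd)],
                T = summ$alpha[which.max(summ$T_sd)])
  structure(list(parameter = "alpha", grid = alpha_grid,
                 replicates = replicates, seed0 = seed0,
                 per_replicate = per, summary = summ, peaks = peaks),
            class = "swarm_sweep")
}

#' Convergence time versus speed and population
#'
#' Runs replicate simulations for every combination of step length `v` and
#' population `P` (the box is rescaled as \eqn{L \propto \sqrt{P}} so all
#' populations start at the density of `base`), records the convergence
#' time, and locates for each `P` the speed minimising the mean
#' convergence time.  Runs hitting `max_sweeps` are censored: counted and
#' reported, never averaged into `t_conv`.  A power law
#' \eqn{t_{conv} \sim c\,P^\gamma} is fitted across populations at their
#' optimal speeds (log-log least squares) and the exponent returned with
#' its standard error.
#'
#' @param base A [swarm_params()].
#' @param v_grid Speeds to scan.
#' @param P_list Population sizes.
#' @param replicates Runs per (v, P) cell.
#' @param seed0 Master seed.
#' @return A `swarm_sweep` with `summary` (per v,P: mean/sd t_conv over
#'   converged runs, censored count), `optimal` (per P) and `fit`
#'   (`gamma`, `se`, `log_c`).
#' @export
sweep_speed <- function(base, v_grid, P_list = base$P, replicates = 10L,
                        seed0 = base$seed) {
  validate_params(base)
  stopifnot(replicates >= 1, all(v_grid > 0), all(P_list >= 1))
  rho <- base$P / base$L^2
  cells <- expand.grid(v = v_grid, P = as.integer(P_list))
  per <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    v <- cells$v[k]; P <- cells$P[k]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      p <- base
      p$v <- v; p$P <- P; p$L <- sqrt(P / rho)
      p$seed <- replicate_seed(seed0, c(param_key(v), P), r)
      tr <- run_swarm(p, sample_every = p$max_sweeps)
      data.frame(v = v, P = P, rep = r, seed = p$seed,
                 converged = tr$converged, t_conv = tr$t_conv,
                 sweeps_run = tr$sweeps_run)
    }))
  }))
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    df <- per[per$v == cells$v[k] & per$P == cells$P[k], ]
    conv <- df[df$converged, ]
    data.frame(v = cells$v[k], P = cells$P[k], replicates = nrow(df),
               n_converged = nrow(conv), n_censored = sum(!df$converged),
               convergence_prob = mean(df$converged),
               t_conv_mean = if (nrow(conv)) mean(conv$t_conv) else NA_real_,
               t_conv_sd = if (nrow(conv) > 1) sd(conv$t_conv) else 0)
  }))
  optimal <- do.call(rbind, lapply(unique(summ$P), function(P) {
    df <- summ[summ$P == P & !is.na(summ$t_conv_mean), ]
    if (!nrow(df)) return(data.frame(P = P, v_opt = NA_real_,
                                     t_conv_opt = NA_real_))
    k <- which.min(df$t_conv_mean)
    data.frame(P = P, v_opt = df$v[k], t_conv_opt = df$t_conv_mean[k])
  }))
  fit <- NULL
  ok <- !is.na(optimal$t_conv_opt) & optimal$t_conv_opt > 0
  if (sum(ok) >= 3) fit <- power_fit(optimal$P[ok], optimal$t_conv_opt[ok])
  structure(list(parameter = "v,P", grid = cells, replicates = replicates,
                 seed0 = seed0, per_replicate = per, summary = summ,
                 optimal = optimal, fit = fit),
            class = "swarm_sweep")
}

# Least-squares power law t = c * P^gamma on log-log scale.
power_fit <- function(P, t) {
  fm <- lm(log(t) ~ log(P))
  list(gamma = unname(coef(fm)[2]),
       se = unname(summary(fm)$coefficients[2, 2]),
       log_c = unname(coef(fm)[1]))
}

#' Noise-strength sweep
#'
#' Runs a fixed number of sweeps (`horizon`; no quasi-stationarity
#' requirement) for every noise strength in the grid and evaluates the
#' order parameters on the final state.  The empirical transition point is
#' the noise strength at which the mean sixfold order parameter crosses
#' 0.5 (linear interpolation between bracketing grid values).
#'
#' @param base A [swarm_params()]; `alpha` should sit in the ordered regime
#'   for the transition to be visible.
#' @param eta_grid Noise strengths in `[0, 1]`.
#' @param horizon Number of sweeps per run (>= 1).
#' @param replicates Runs per grid value.
#' @param seed0 Master seed.
#' @param r_T_factor,link_factor Metric conventions, see [swarm_metrics()].
#' @return A `swarm_sweep` with `summary` (per eta) and `eta_c` (the 0.5
#'   crossing, `NA` when the grid never crosses).
#' @export
sweep_noise <- function(base, eta_grid, horizon = 2000L, replicates = 10L,
                        seed0 = base$seed, r_T_factor = 1.3,
                        link_factor = 1.5) {
  validate_params(base)
  stopifnot(horizon >= 1, replicates >= 1,
            all(eta_grid >= 0 & eta_grid <= 1))
  per <- do.call(rbind, lapply(eta_grid, function(e) {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      p <- base
      p$eta <- e
      p$max_sweeps <- as.integer(horizon)
      p$qs_window <- as.integer(horizon + 1L)  # never stop early
      p$seed <- replicate_seed(seed0, param_key(e), r)
      cbind(data.frame(eta = e, rep = r),
            run_replicate(p, r_T_factor, link_factor))
    }))
  }))
  summ <- do.call(rbind, lapply(eta_grid, function(e)
    cbind(data.frame(eta = e), summarise_cell(per[per$eta == e, ]))))
  eta_c <- NA_real_
  below <- which(summ$psi6_mean < 0.5)
  if (length(below) && below[1] > 1) {
    k <- below[1]
    x0 <- summ$eta[k - 1]; x1 <- summ$eta[k]
    y0 <- summ$psi6_mean[k - 1]; y1 <- summ$psi6_mean[k]
    eta_c <- x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0)
  } else if (length(below)) {
    eta_c <- summ$eta[1]
  }
  structure(list(parameter = "eta", grid = eta_grid, horizon = horizon,
                 replicates = replicates, seed0 = seed0,
                 per_replicate = per, summary = summ, eta_c = eta_c),
            class = "swarm_sweep")
}

#' @export
print.swarm_sweep <- function(x, ...) {
  cat(sprintf("swarm_sweep over %s: %d grid value(s) x %d replicate(s)\n",
              x$parameter,
              if (is.data.frame(x$grid)) nrow(x$grid) else length(x$grid),
              x$replicates))
  print(x$summary, digits = 4)
  invisible(x)
}

# Area of the occupied region: the convex hull of the swarm inflated by D/2.
# Equals the sum of the hull-clipped Voronoi areas without tessellating.
occupied_area <- function(positions, D) {
  poly_area(region_from_hull(positions, inflate = D / 2)$verts)
}

#' Selfish-herd scenario
#'
#' Runs the crab-swarm parameterisation — `P = 90` individuals with `D`
#' equal to the mean inter-individual distance after an attack and `v` the
#' mean attack speed, in model units — and tracks the total
#' domain-of-danger area \eqn{A(t)} (occupied-region convention)
#' normalised by its initial value.  A movement rule solves the selfish
#' herd problem when \eqn{A(t)/A(0)} drops quickly to a small plateau.
#'
#' @param params A [swarm_params()]; defaults to the crab parameterisation
#'   with a small attention field and mild direction noise.
#' @param horizon Length of the reported time series, sweeps.
#' @param seed RNG seed (overrides `params$seed`).
#' @return A list of class `herd_scenario`: `ts`, `A_norm`
#'   (\eqn{A(t)/A(0)}), `reduction_horizon` and `reduction_qs` (mean-area
#'   reduction at the horizon and at quasi-stationarity, `NA` when the run
#'   did not converge), `trajectory`.
#' @export
herd_scenario <- function(params = swarm_params(P = 90L, alpha = pi / 2,
                                                eta = 0.1),
                          horizon = 600L, seed = params$seed) {
  validate_params(params)
  stopifnot(horizon >= 1)
  params$seed <- as.integer(seed)
  params$max_sweeps <- as.integer(min(params$max_sweeps, horizon))
  tr <- run_swarm(params, sample_every = 1L)
  A <- vapply(tr$samples, occupied_area, numeric(1), D = params$D)
  A_norm <- A / A[1]
  structure(list(ts = tr$ts, A_norm = A_norm,
                 reduction_horizon = 1 - A_norm[length(A_norm)],
                 reduction_qs = if (tr$converged) 1 - A_norm[length(A_norm)] else NA_real_,
                 converged = tr$converged, t_conv = tr$t_conv,
                 trajectory = tr),
            class = "herd_scenario")
}

#' @export
print.herd_scenario <- function(x, ...) {
  cat(sprintf("herd_scenario: %d sampled sweeps, A(end)/A(0) = %.3f\n",
              length(x$ts), x$A_norm[length(x$A_norm)]))
  cat(sprintf("  reduction at horizon = %.1f%%, at quasi-stationarity = %s\n",
              100 * x$reduction_horizon,
              ifelse(is.na(x$reduction_qs), "NA",
                     sprintf("%.1f%%", 100 * x$reduction_qs))))
  invisible(x)
}
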