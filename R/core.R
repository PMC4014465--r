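#' Swarm state constructor
#'
#' A swarm state is the list of the `P` agent positions inside the box plus
#' the elapsed time (completed sweeps).  Positions are a `P x 2` matrix.
#'
#' @param positions Numeric `P x 2` matrix of coordinates.
#' @param t Elapsed time units (sweeps completed).
#' @param L Box side; every coordinate must lie in `[0, L]`.
#' @return An object of class `swarm_state`.
#' @export
swarm_state <- function(positions, t = 0L, L = Inf) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("positions must be a P x 2 matrix")
  storage.mode(positions) <- "double"
  if (anyNA(positions)) stop("positions contain NA")
  if (any(positions < 0) || any(positions > L))
    stop("positions outside [0, L] x [0, L]")
  structure(list(positions = positions, t = as.integer(t)),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("swarm_state: %d agents at t = %d\n", nrow(x$positions), x$t))
  invisible(x)
}

#' Uniform random initial condition
#'
#' Draws `P` independent positions uniformly in the box `[0, L]^2` (the
#' initial condition used in all experiments; density `P / L^2` by
#' construction).  Coincident pairs — a probability-zero accident — are
#' redrawn so the initial state never holds duplicate points.
#'
#' @param params A [swarm_params()] object.
#' @return A [swarm_state()] at `t = 0`.
#' @examples
#' set.seed(1)
#' st <- init_uniform(swarm_params(P = 10))
#' range(st$positions)
#' @export
init_uniform <- function(params) {
  validate_params(params)
  repeat {
    pos <- cbind(runif(params$P, 0, params$L), runif(params$P, 0, params$L))
    if (params$P < 2L || !anyDuplicated(pos[, 1] + 1i * pos[, 2])) break
  }
  swarm_state(pos, t = 0L, L = params$L)
}

#' Draw gaze directions
#'
#' Gazing directions are uniform on `[0, 2*pi)`; each one bisects the
#' attention sector of amplitude `alpha` inside which the agent searches for
#' its nearest neighbour.
#'
#' @param n Number of draws.
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
sample_gaze <- function(n = 1L) {
  runif(n, 0, 2 * pi)
}

#' Nearest neighbour inside the attention sector
#'
#' Returns the index of the agent nearest to agent `i` among those whose
#' bearing from `i` lies in the closed sector `[gaze - alpha/2,
#' gaze + alpha/2]` (angles modulo `2*pi`), or `NA` when the sector is
#' empty.  With `alpha = 2*pi` this is the global nearest neighbour
#' (Hamilton's rule).  Equidistant candidates resolve to the lowest index.
#'
#' @param state A [swarm_state()] or a `P x 2` position matrix.
#' @param i Focal agent index (1-based).
#' @param gaze Gaze direction, radians.
#' @param alpha Sector amplitude, radians in `(0, 2*pi]`.
#' @return Integer index or `NA_integer_`.
#' @examples
#' pos <- rbind(c(0, 0), c(1, 0), c(0.1, 0.9))
#' sector_nearest_neighbour(pos, 1, gaze = 0, alpha = pi / 2)  # 2
#' @export
sector_nearest_neighbour <- function(state, i, gaze, alpha) {
  pos <- if (inherits(state, "swarm_state")) state$positions else as.matrix(state)
  stopifnot(i >= 1, i <= nrow(pos), alpha > 0, alpha <= 2 * pi)
  j <- cpp_sector_nn(pos, as.integer(i), gaze, alpha)
  if (j == 0L) NA_integer_ else j
}

#' Move one agent relative to a chosen neighbour
#'
#' The deterministic core: if the distance `d` to the neighbour exceeds `D`
#' the agent steps `v` toward it, stopping exactly on the circle of radius
#' `D` when the step would invade the stress zone; if `d < D` it steps `v`
#' directly away, stopping at distance `D` when it would overshoot; at
#' `d = D` it stays put.  With `eta > 0` the movement direction is first
#' rotated by an angle uniform on `[-eta*pi, eta*pi]` (one RNG draw) and the
#' same stop-at-`D` rule applies along the noisy path.  The final position is
#' clamped to the box.
#'
#' @inheritParams sector_nearest_neighbour
#' @param j Neighbour index, `j != i`.
#' @param params A [swarm_params()] object (uses `D`, `v`, `eta`, `L`, `dtol`).
#' @return A list of class `step_outcome`: `state` (updated), `agent_index`,
#'   `moved`, `displacement_norm`, `clamped`.
#' @examples
#' st <- swarm_state(rbind(c(0, 0), c(1, 0)))
#' p <- swarm_params(P = 2, L = 10, D = 0.1, v = 0.3)
#' move_agent(st, 1, 2, p)$state$positions[1, ]  # (0.3, 0)
#' @export
move_agent <- function(state, i, j, params) {
  if (!inherits(state, "swarm_state")) state <- swarm_state(state)
  validate_params(params)
  if (i == j) stop("i and j must differ")
  r <- cpp_move_agent(state$positions, as.integer(i), as.integer(j),
                      params$D, params$v, params$eta, params$L, params$dtol)
  state$positions[i, ] <- c(r$x, r$y)
  structure(list(state = state, agent_index = as.integer(i),
                 moved = r$moved, displacement_norm = r$displacement,
                 clamped = r$clamped),
            class = "step_outcome")
}

#' One asynchronous sweep
#'
#' Performs `P` single-agent updates in sequence — each on a uniformly
#' random agent (with replacement by default), each drawing a fresh gaze and
#' seeing the positions left by all previous updates — and advances the
#' clock by one time unit.  Agents with an empty attention sector stay put.
#'
#' @param state A [swarm_state()].
#' @param params A [swarm_params()] object.
#' @return List with `state` (updated, `t` advanced by 1), `moved`
#'   (count of updates that displaced an agent, in `[0, P]`) and
#'   `clamp_events` (boundary clamps during this sweep).
#' @export
sweep_agents <- function(state, params) {
  if (!inherits(state, "swarm_state")) state <- swarm_state(state)
  validate_params(params)
  stopifnot(nrow(state$positions) == params$P)
  r <- cpp_sweep(state$positions, params$L, params$D, params$v, params$alpha,
                 params$eta, params$select == "permutation", params$dtol)
  list(state = swarm_state(r$positions, t = state$t + 1L, L = params$L),
       moved = r$moved, clamp_events = r$clamp_events)
}

#' Run a simulation to quasi-stationarity
#'
#' Seeds the RNG from `params$seed`, draws the uniform initial condition
#' (unless `init` is given) and iterates sweeps until either `qs_window`
#' consecutive sweeps record no position change (the quasi-stationary
#' criterion; `converged = TRUE` with `t_conv` the sweep at which movement
#' last occurred) or `max_sweeps` is reached (`converged = FALSE`, a
#' reported outcome, not an error).  States are sampled every `sample_every`
#' sweeps plus the initial and final states.
#'
#' @param params A [swarm_params()] object.
#' @param sample_every Sampling stride in sweeps.
#' @param init Optional [swarm_state()] initial condition; default uniform.
#' @return An object of class `swarm_trajectory`: `params`, `seed`,
#'   `ts` (sample times), `samples` (list of position matrices),
#'   `converged`, `t_conv`, `sweeps_run`, `clamp_events`, `moved_counts`.
#' @examples
#' \donttest{
#' tr <- run_swarm(swarm_params(P = 20, L = 0.8, seed = 7), sample_every = 500)
#' tr$converged
#' }
#' @export
run_swarm <- function(params, sample_every = 100L, init = NULL) {
  validate_params(params)
  stopifnot(sample_every >= 1L)
  set.seed(params$seed)
  st <- if (is.null(init)) init_uniform(params) else init
  if (!inherits(st, "swarm_state")) st <- swarm_state(st, L = params$L)
  stopifnot(nrow(st$positions) == params$P)
  r <- cpp_run(st$positions, params$L, params$D, params$v, params$alpha,
               params$eta, params$select == "permutation",
               params$qs_window, params$max_sweeps, as.integer(sample_every),
               params$dtol)
  structure(list(params = params, seed = params$seed,
                 ts = as.integer(r$ts), samples = r$samples,
                 converged = r$converged,
                 t_conv = if (is.na(r$t_conv)) NA_integer_ else as.integer(r$t_conv),
                 sweeps_run = as.integer(r$sweeps_run),
                 clamp_events = as.integer(r$clamp_events),
                 moved_counts = as.integer(r$moved_counts)),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat(sprintf(
    "swarm_trajectory: P = %d, alpha = %.3f rad, eta = %g, seed = %d\n",
    x$params$P, x$params$alpha, x$params$eta, x$seed))
  cat(sprintf("  %d sweeps run, %d samples, converged = %s%s\n",
              x$sweeps_run, length(x$ts), x$converged,
              if (isTRUE(x$converged)) sprintf(" (t_conv = %d)", x$t_conv) else ""))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj A `swarm_trajectory`.
#' @return A [swarm_state()] holding the last sampled configuration.
#' @export
final_state <- function(traj) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  n <- length(traj$samples)
  swarm_state(traj$samples[[n]], t = traj$ts[n])
}

#' Absorbing-state test
#'
#' A configuration is an (effective) absorbing state when every pair of
#' topological neighbours — agents whose Voronoi polygons share an edge —
#' sits at distance exactly `D`.  Degenerate geometries (fewer than 3
#' points, collinear points) are reported as not absorbing.
#'
#' @param state A [swarm_state()] or position matrix.
#' @param D Ideal inter-individual distance.
#' @param tol Absolute tolerance on the distances.
#' @param box Optional `c(xmin, xmax, ymin, ymax)` clipping rectangle;
#'   defaults to the bounding box of the points.
#' @return Logical.
#' @export
is_absorbing <- function(state, D, tol = 1e-9, box = NULL) {
  pos <- if (inherits(state, "swarm_state")) state$positions else as.matrix(state)
  if (nrow(pos) < 2L) stop("need at least 2 agents")
  g <- tryCatch(voronoi_topological_graph(pos, box = box),
                error = function(e) NULL)
  if (is.null(g)) return(FALSE)
  d <- sqrt(rowSums((pos[g$edges[, 1], , drop = FALSE] -
                     pos[g$edges[, 2], , drop = FALSE])^2))
  all(abs(d - D) <= tol)
}
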