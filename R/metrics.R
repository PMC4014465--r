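#' Per-agent sixfold bond-orientational order
#'
#' For agent `i` with topological neighbours `j` (Voronoi polygons sharing
#' an edge), \eqn{\psi_6(i) = N_i^{-1} \sum_j e^{6 i \theta_{ij}}} where
#' \eqn{\theta_{ij}} is the angle of the bond to the positive x-axis (the
#' reference axis is irrelevant to the global norm).  The factor 6 makes
#' the statistic equal 1 exactly when the six bonds sit at 60-degree
#' increments, i.e. on a triangular lattice.
#'
#' @param positions `P x 2` matrix or [swarm_state()].
#' @param graph A [voronoi_topological_graph()]; computed if missing.
#' @param ... Passed to [voronoi_topological_graph()] when `graph` is `NULL`.
#' @return Complex vector of length `P` (`NA` for agents without neighbours).
#' @export
psi6_local <- function(positions, graph = NULL, ...) {
  pos <- if (inherits(positions, "swarm_state")) positions$positions else as.matrix(positions)
  if (is.null(graph)) graph <- voronoi_topological_graph(pos, ...)
  acc <- complex(nrow(pos))
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    th <- atan2(pos[j, 2] - pos[i, 2], pos[j, 1] - pos[i, 1])
    e <- exp(6i * th)          # exp(6i(th+pi)) = exp(6i th): bond symmetric
    acc[i] <- acc[i] + e
    acc[j] <- acc[j] + e
  }
  out <- acc / graph$degree
  out[graph$degree == 0L] <- NA_complex_
  out
}

#' Global sixfold positional-orientational order parameter
#'
#' The norm of the average of the per-agent \eqn{\psi_6} over the swarm:
#' 1 on a perfect triangular lattice, small (order \eqn{n^{-1/2}}) for
#' random points.  Invariant under global translations and rotations of the
#' point set.
#'
#' Two rim conventions are provided.  `"clipped"` clips polygons to the box
#' and averages over all agents — comparable across attention-angle sweeps.
#' `"interior"` clips to the convex hull of the points and averages only
#' over agents whose polygon does not touch the hull, removing the rim
#' cells whose bond count is distorted by the swarm's edge; this is the
#' convention under which a finite crystal patch scores exactly 1.
#'
#' @inheritParams psi6_local
#' @param box Clipping rectangle for the `"clipped"` convention (side
#'   length, 4-vector, or `NULL` for the bounding box).
#' @param convention `"clipped"` or `"interior"`.
#' @return A number in `[0, 1]`.
#' @examples
#' hexa <- make_triangular_lattice(0.1, shells = 1)
#' psi6_global(hexa$positions, convention = "interior")  # 1
#' @export
psi6_global <- function(positions, box = NULL,
                        convention = c("clipped", "interior")) {
  convention <- match.arg(convention)
  pos <- if (inherits(positions, "swarm_state")) positions$positions else as.matrix(positions)
  if (convention == "clipped") {
    g <- voronoi_topological_graph(pos, box = box, clip = "box")
    keep <- rep(TRUE, nrow(pos))
  } else {
    g <- voronoi_topological_graph(pos, clip = "hull")
    keep <- !g$boundary
    if (!any(keep))
      stop("degenerate input: no interior agents under the hull convention")
  }
  if (any(g$degree[keep] == 0L))
    stop("degenerate input: agent without topological neighbours")
  psi <- psi6_local(pos, graph = g)
  Mod(mean(psi[keep]))
}

#' Translational order parameter
#'
#' Mean over agents of the number of individuals contained in the circle of
#' radius `r_T` around each agent.  The focal individual is counted by
#' default, so an isolated agent scores 1, isolated pairs at spacing below
#' `r_T` score 2 (the fragmented-phase plateau) and the interior of a
#' triangular lattice with `D < r_T < sqrt(3) D` scores 7.
#'
#' @param positions `P x 2` matrix or [swarm_state()].
#' @param r_T Counting radius, length units.  A radius strictly between the
#'   first (`D`) and second (`sqrt(3) D`) lattice shells — the default used
#'   throughout the experiments is `1.3 * D` — separates the crystal,
#'   liquid-like and fragmented arrangements.
#' @param include_self Count the focal individual (default `TRUE`).
#' @return A number (>= 1 when `include_self`).
#' @export
translational_T <- function(positions, r_T, include_self = TRUE) {
  pos <- if (inherits(positions, "swarm_state")) positions$positions else as.matrix(positions)
  stopifnot(r_T > 0)
  n <- nrow(pos)
  if (n == 1L) return(if (include_self) 1 else 0)
  dm <- as.matrix(dist(pos))
  counts <- rowSums(dm <= r_T) - 1L   # dist diagonal is 0: remove self
  mean(counts) + if (include_self) 1 else 0
}

#' Reduction of the mean domain-of-danger area
#'
#' Compares the mean Voronoi polygon area of a final configuration against
#' the initial one: `1 - mean_area(final) / mean_area(initial)`.  With the
#' occupied-region convention (polygons clipped to the convex hull of the
#' point set inflated by `D/2`, the default) compaction of the swarm
#' registers as a positive reduction; the plain box clip is available for
#' reference but is dominated by empty arena at the rim.
#'
#' @param initial,final `P x 2` matrices or [swarm_state()] objects with the
#'   same number of agents.
#' @param D Stress-zone radius; the hull is inflated by `D/2`.
#' @param box Clipping rectangle for `clip = "box"`.
#' @param clip `"hull"` (occupied region, default) or `"box"`.
#' @return The fractional reduction (1 would mean vanishing final area;
#'   negative values mean expansion).
#' @export
area_reduction <- function(initial, final, D, box = NULL,
                           clip = c("hull", "box")) {
  clip <- match.arg(clip)
  a0 <- voronoi_areas(initial, box = box, clip = clip,
                      inflate = if (clip == "hull") D / 2 else 0)
  a1 <- voronoi_areas(final, box = box, clip = clip,
                      inflate = if (clip == "hull") D / 2 else 0)
  if (length(a0) != length(a1)) stop("initial and final must have the same n")
  1 - mean(a1) / mean(a0)
}

#' Cluster decomposition at a linking distance
#'
#' Connected components of the graph joining every pair of agents closer
#' than `link_dist`.  Labels are positive integers in order of first
#' appearance, so the labelling is deterministic.
#'
#' @param positions `P x 2` matrix or [swarm_state()].
#' @param link_dist Linking distance (> 0); the sweep experiments use
#'   `1.5 * D`.
#' @return Integer vector of cluster labels, one per agent.
#' @export
cluster_components <- function(positions, link_dist) {
  pos <- if (inherits(positions, "swarm_state")) positions$positions else as.matrix(positions)
  stopifnot(link_dist > 0)
  n <- nrow(pos)
  if (n == 1L) return(1L)
  dm <- as.matrix(dist(pos))
  adj <- dm < link_dist
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  as.integer(match(memb, unique(memb)))
}

#' Order metrics of one configuration
#'
#' Evaluates the full measurement record on a single state: the global
#' sixfold order parameter, the translational parameter, the mean and total
#' domain-of-danger areas (occupied-region convention) and the number of
#' clusters.
#'
#' @param state A [swarm_state()] or `P x 2` matrix.
#' @param params A [swarm_params()] (supplies `D`, `L`).
#' @param r_T_factor Radius of the translational circle in units of `D`.
#' @param link_factor Cluster linking distance in units of `D`.
#' @param psi6_convention Passed to [psi6_global()].
#' @return A one-row `data.frame`: `t`, `psi6`, `T`, `mean_area`,
#'   `total_area`, `n_clusters`.
#' @export
swarm_metrics <- function(state, params, r_T_factor = 1.3,
                          link_factor = 1.5,
                          psi6_convention = "clipped") {
  pos <- if (inherits(state, "swarm_state")) state$positions else as.matrix(state)
  t <- if (inherits(state, "swarm_state")) state$t else NA_integer_
  areas <- voronoi_areas(pos, clip = "hull", inflate = params$D / 2)
  data.frame(
    t = t,
    psi6 = psi6_global(pos, box = params$L, convention = psi6_convention),
    T = translational_T(pos, r_T = r_T_factor * params$D),
    mean_area = mean(areas),
    total_area = sum(areas),
    n_clusters = max(cluster_components(pos, link_factor * params$D))
  )
}
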