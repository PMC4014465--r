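# Analytic test configurations.  Every fixture carries its closed-form
# expectations (lattice geometry), never simulation output.

#' Hexagonal patch of a triangular lattice
#'
#' Builds the centred hexagonal patch with `1 + 3*shells*(shells+1)` points
#' of a triangular lattice: the densest packing compatible with a pairwise
#' distance `spacing`, and the configuration the swarm crystallises into in
#' the ordered regime.  Expectations are analytic: interior
#' nearest-neighbour distance equal to the spacing, interior Voronoi cell
#' area \eqn{(\sqrt{3}/2)\,a^2}, interior sixfold order exactly 1.
#'
#' @param spacing Lattice constant `a` (> 0).
#' @param shells Number of hexagonal shells around the centre (>= 1);
#'   `shells = 1` is the hexagon-plus-centre motif (7 points).
#' @param center Centre of the patch.
#' @param angle Rigid rotation of the patch, radians.
#' @return A list of class `swarm_fixture`: `name`, `positions`
#'   (`n x 2` matrix) and `expected` (named list of analytic values).
#' @examples
#' nrow(make_triangular_lattice(0.1, shells = 5)$positions)  # 91
#' @export
make_triangular_lattice <- function(spacing, shells, center = c(0, 0),
                                    angle = 0) {
  stopifnot(spacing > 0, shells >= 1)
  s <- as.integer(shells)
  idx <- expand.grid(n1 = -s:s, n2 = -s:s)
  idx <- idx[pmax(abs(idx$n1), abs(idx$n2), abs(idx$n1 + idx$n2)) <= s, ]
  e1 <- c(1, 0); e2 <- c(0.5, sqrt(3) / 2)
  pos <- spacing * (outer(idx$n1, e1) + outer(idx$n2, e2))
  if (angle != 0) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
    pos <- pos %*% t(R)
  }
  pos <- cbind(pos[, 1] + center[1], pos[, 2] + center[2])
  structure(list(
    name = sprintf("triangular_lattice_s%d", s),
    positions = pos,
    expected = list(
      n = 1L + 3L * s * (s + 1L),
      nn_distance = spacing,
      psi6_interior = 1,
      interior_cell_area = sqrt(3) / 2 * spacing^2,
      hull_area = 3 * sqrt(3) / 2 * (s * spacing)^2
    )), class = "swarm_fixture")
}

#' Isolated pairs fixture
#'
#' `n_pairs` pairs of agents at distance `spacing` within each pair, with
#' consecutive pairs `gap` apart along the x-axis.  With a counting radius
#' between `spacing` and `gap - spacing` the translational parameter is
#' exactly 2 — the fragmented-phase plateau.
#'
#' @param n_pairs Number of pairs.
#' @param spacing Intra-pair distance.
#' @param gap Distance between consecutive pair anchors (> 2 * spacing).
#' @return A `swarm_fixture`.
#' @export
make_isolated_pairs <- function(n_pairs, spacing, gap = 10 * spacing) {
  stopifnot(n_pairs >= 1, spacing > 0, gap > 2 * spacing)
  x0 <- (seq_len(n_pairs) - 1) * gap
  y0 <- ((seq_len(n_pairs) - 1) %% 2) * gap  # stagger rows: not collinear
  pos <- rbind(cbind(x0, y0), cbind(x0 + spacing, y0))
  structure(list(name = sprintf("isolated_pairs_%d", n_pairs),
                 positions = pos,
                 expected = list(n = 2L * n_pairs, T_plateau = 2)),
            class = "swarm_fixture")
}

#' Uniform random cloud fixture
#'
#' `n` points i.i.d. uniform on `[0, L]^2`, drawn from the current RNG
#' state (seed it with `set.seed()` for reproducibility).
#'
#' @param n Number of points.
#' @param L Box side.
#' @return A `swarm_fixture` (expected: density `n / L^2`).
#' @export
make_uniform_cloud <- function(n, L) {
  stopifnot(n >= 1, L > 0)
  structure(list(name = sprintf("uniform_cloud_%d", n),
                 positions = cbind(runif(n, 0, L), runif(n, 0, L)),
                 expected = list(n = as.integer(n), density = n / L^2)),
            class = "swarm_fixture")
}
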