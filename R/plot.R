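#' Plot a swarm configuration
#'
#' Scatter of agent positions, optionally with the Voronoi tessellation
#' overlaid.
#'
#' @param x A [swarm_state()].
#' @param voronoi Draw the box-clipped Voronoi cells.
#' @param box Box side `L` (or 4-vector) for the axes and the tessellation.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.swarm_state <- function(x, voronoi = FALSE, box = NULL, ...) {
  pos <- x$positions
  if (is.null(box)) box <- c(range(pos[, 1]), range(pos[, 2]))
  if (length(box) == 1L) box <- c(0, box, 0, box)
  graphics::plot(pos, xlim = box[1:2], ylim = box[3:4], asp = 1,
                 pch = 19, cex = 0.6, col = "red3",
                 xlab = "x", ylab = "y",
                 main = sprintf("t = %d", x$t), ...)
  if (voronoi && nrow(pos) >= 3L) {
    tess <- voronoi_tessellation(pos, box = box)
    for (cell in tess$cells)
      if (nrow(cell$verts) >= 3L)
        graphics::polygon(cell$verts, border = "grey60")
  }
  invisible(x)
}

#' Plot a parameter sweep
#'
#' Mean of an order parameter versus the swept parameter with one-standard-
#' deviation error bars.
#'
#' @param x A `swarm_sweep` from [sweep_alpha()] or [sweep_noise()].
#' @param metric Column prefix in the summary, e.g. `"psi6"` or `"T"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.swarm_sweep <- function(x, metric = "psi6", ...) {
  s <- x$summary
  xcol <- intersect(c("alpha", "eta", "v"), names(s))[1]
  xv <- s[[xcol]]
  mu <- s[[paste0(metric, "_mean")]]
  sdv <- s[[paste0(metric, "_sd")]]
  if (is.null(mu)) stop("metric not found in sweep summary: ", metric)
  graphics::plot(xv, mu, type = "b", pch = 19,
                 ylim = range(c(mu - sdv, mu + sdv)),
                 xlab = x$parameter, ylab = metric, ...)
  graphics::arrows(xv, mu - sdv, xv, mu + sdv, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}

#' Plot a selfish-herd scenario
#'
#' Time evolution of the total domain-of-danger area normalised by its
#' initial value.
#'
#' @param x A [herd_scenario()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.herd_scenario <- function(x, ...) {
  graphics::plot(x$ts, x$A_norm, type = "l", xlab = "t (sweeps)",
                 ylab = "A(t) / A(0)", ...)
  invisible(x)
}
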