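# Voronoi cells by incremental half-plane clipping.
#
# Each agent's cell starts as the (convex) clipping region and is cut by the
# perpendicular bisector against other agents in order of increasing
# distance; once every remaining agent is farther than twice the cell's
# current circumradius no further cut can touch the cell, so the scan stops
# early (O(k) cuts per cell in practice).  Every cell edge carries a label:
# the index of the neighbour whose bisector created it, or 0 for a piece of
# the region boundary.  Topological adjacency, polygon areas and the
# interior/rim distinction all read off these labels.

# region: list(verts = k x 2 CCW matrix, labels = integer k), labels[k] is
# the label of the edge verts[k] -> verts[k+1 (mod k)].

region_from_box <- function(box) {
  if (length(box) == 1L) box <- c(0, box, 0, box)
  stopifnot(length(box) == 4L, box[2] > box[1], box[4] > box[3])
  list(verts = rbind(c(box[1], box[3]), c(box[2], box[3]),
                     c(box[2], box[4]), c(box[1], box[4])),
       labels = rep(0L, 4L))
}

region_from_hull <- function(positions, inflate = 0, k_arc = 16L) {
  pts <- as.matrix(positions)
  h <- chull(pts)                       # clockwise
  if (length(h) < 3L) stop("degenerate geometry: points are collinear")
  hv <- pts[rev(h), , drop = FALSE]     # counter-clockwise
  if (inflate > 0) {
    ang <- seq(0, 2 * pi, length.out = k_arc + 1L)[-(k_arc + 1L)]
    circ <- inflate * cbind(cos(ang), sin(ang))
    cand <- do.call(rbind, lapply(seq_len(nrow(hv)), function(k)
      sweep_add(circ, hv[k, ])))
    h2 <- chull(cand)
    hv <- cand[rev(h2), , drop = FALSE]
  }
  list(verts = hv, labels = rep(0L, nrow(hv)))
}

sweep_add <- function(m, v) cbind(m[, 1] + v[1], m[, 2] + v[2])

# Clip a labelled convex polygon by the half-plane {x : n.x <= c}.
# new_label marks edges created on the cut line.
clip_halfplane <- function(verts, labels, n, c, new_label, eps) {
  K <- nrow(verts)
  f <- verts %*% n - c
  if (all(f <= eps)) return(list(verts = verts, labels = labels))
  if (all(f > eps)) return(list(verts = verts[0, , drop = FALSE],
                                labels = integer(0)))
  outv <- matrix(0, K + 2L, 2L)
  outl <- integer(K + 2L)
  m <- 0L
  for (k in seq_len(K)) {
    k2 <- if (k == K) 1L else k + 1L
    fa <- f[k]; fb <- f[k2]
    ain <- fa <= eps; bin <- fb <= eps
    if (ain) {
      m <- m + 1L; outv[m, ] <- verts[k, ]; outl[m] <- labels[k]
      if (!bin) { # exit point: next edge runs along the bisector
        t <- fa / (fa - fb)
        m <- m + 1L
        outv[m, ] <- verts[k, ] + t * (verts[k2, ] - verts[k, ])
        outl[m] <- new_label
      }
    } else if (bin) { # entry point: edge continues toward b on the old line
      t <- fa / (fa - fb)
      m <- m + 1L
      outv[m, ] <- verts[k, ] + t * (verts[k2, ] - verts[k, ])
      outl[m] <- labels[k]
    }
  }
  dedupe_poly(outv[seq_len(m), , drop = FALSE], outl[seq_len(m)], eps)
}

# Drop zero-length edges, keeping the label of the edge that leaves the
# surviving vertex.
dedupe_poly <- function(verts, labels, eps) {
  m <- nrow(verts)
  if (m < 2L) return(list(verts = verts, labels = labels))
  keep <- rep(TRUE, m)
  for (k in 2:m) {
    if (sum(abs(verts[k, ] - verts[k - 1L, ])) <= eps) keep[k - 1L] <- FALSE
  }
  if (sum(abs(verts[m, ] - verts[1L, ])) <= eps && keep[m]) keep[m] <- FALSE
  list(verts = verts[keep, , drop = FALSE], labels = labels[keep])
}

poly_area <- function(verts) {
  k <- nrow(verts)
  if (is.null(k) || k < 3L) return(0)
  x <- verts[, 1]; y <- verts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Voronoi tessellation clipped to a convex region
#'
#' Computes every agent's Voronoi polygon intersected with a convex clipping
#' region: either the box (rectangle) or the convex hull of the point set,
#' optionally inflated by a margin (the Minkowski sum with a disk,
#' approximated by a 16-gon).  The hull clip with `inflate = D/2` is the
#' "occupied region" convention used for domain-of-danger areas: it measures
#' the space the swarm actually covers instead of crediting rim agents with
#' the empty arena.
#'
#' @param positions `P x 2` position matrix or [swarm_state()].
#' @param box Clipping rectangle for `clip = "box"`: a side length `L`
#'   (meaning `[0, L]^2`), a `c(xmin, xmax, ymin, ymax)` vector, or `NULL`
#'   for the bounding box of the points.
#' @param clip `"box"` or `"hull"`.
#' @param inflate Margin added around the hull (hull clip only), length units.
#' @return Object of class `voronoi_tess`: list with `cells` (per agent:
#'   `verts`, `labels`, `area`), `region`, `areas` (numeric vector) and `n`.
#' @export
voronoi_tessellation <- function(positions, box = NULL,
                                 clip = c("box", "hull"), inflate = 0) {
  clip <- match.arg(clip)
  pos <- if (inherits(positions, "swarm_state")) positions$positions else as.matrix(positions)
  n <- nrow(pos)
  if (n < 3L) stop("degenerate geometry: need at least 3 points")
  cent <- sweep_add(pos, -colMeans(pos))
  if (min(svd(cent, nu = 0, nv = 0)$d) < 1e-12 * max(1, max(abs(pos))))
    stop("degenerate geometry: points are collinear")
  region <- if (clip == "box") {
    if (is.null(box)) box <- c(range(pos[, 1]), range(pos[, 2]))
    region_from_box(box)
  } else {
    region_from_hull(pos, inflate = inflate)
  }
  scale <- max(1, max(abs(region$verts)))
  eps <- 1e-10 * scale

  # distance-ranked candidate lists shared by all cells
  ord <- lapply(seq_len(n), function(i) {
    d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
    o <- order(d2)
    o <- o[o != i]
    list(o = o, d2 = d2[o])
  })

  cells <- vector("list", n)
  for (i in seq_len(n)) {
    verts <- region$verts; labels <- region$labels
    oi <- ord[[i]]
    r2max <- max((verts[, 1] - pos[i, 1])^2 + (verts[, 2] - pos[i, 2])^2)
    for (k in seq_along(oi$o)) {
      if (oi$d2[k] > 4 * r2max) break
      j <- oi$o[k]
      nvec <- pos[j, ] - pos[i, ]
      cval <- sum(nvec * (pos[i, ] + pos[j, ])) / 2
      cl <- clip_halfplane(verts, labels, nvec, cval, j,
                           eps * sqrt(sum(nvec^2)))
      verts <- cl$verts; labels <- cl$labels
      if (nrow(verts) < 3L) break
      r2max <- max((verts[, 1] - pos[i, 1])^2 + (verts[, 2] - pos[i, 2])^2)
    }
    cells[[i]] <- list(verts = verts, labels = labels,
                       area = poly_area(verts))
  }
  structure(list(cells = cells, region = region, n = n,
                 areas = vapply(cells, `[[`, numeric(1), "area")),
            class = "voronoi_tess")
}

# Edge lengths of a labelled polygon.
cell_edge_lengths <- function(cell) {
  v <- cell$verts
  k <- nrow(v)
  if (k < 2L) return(numeric(0))
  sqrt(rowSums((v[c(2:k, 1L), , drop = FALSE] - v)^2))
}

#' Topological neighbour graph from the Voronoi tessellation
#'
#' Two agents are topological neighbours when their Voronoi polygons,
#' clipped to the region, share an edge of positive length (polygons that
#' meet only at a vertex — four co-circular points — are not neighbours).
#'
#' @inheritParams voronoi_tessellation
#' @param tess Optionally, a precomputed [voronoi_tessellation()].
#' @return Object of class `topological_graph`: `n`, `edges` (m x 2 matrix,
#'   `edges[, 1] < edges[, 2]`), `degree` (per-agent neighbour count
#'   \eqn{N_i}), `boundary` (logical: cell touches the clipping region).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' voronoi_topological_graph(sq, box = c(-1, 2, -1, 2))$edges  # 4 edges
#' @export
voronoi_topological_graph <- function(positions, box = NULL,
                                      clip = c("box", "hull"), inflate = 0,
                                      tess = NULL) {
  if (is.null(tess))
    tess <- voronoi_tessellation(positions, box = box,
                                 clip = match.arg(clip), inflate = inflate)
  scale <- max(1, max(abs(tess$region$verts)))
  len_tol <- 1e-8 * scale
  pairs <- matrix(integer(0), 0L, 2L)
  boundary <- logical(tess$n)
  for (i in seq_len(tess$n)) {
    cell <- tess$cells[[i]]
    if (nrow(cell$verts) < 3L) { boundary[i] <- TRUE; next }
    len <- cell_edge_lengths(cell)
    real <- len > len_tol
    boundary[i] <- any(cell$labels[real] == 0L)
    js <- cell$labels[real & cell$labels > 0L]
    if (length(js))
      pairs <- rbind(pairs, cbind(pmin(i, js), pmax(i, js)))
  }
  edges <- unique(pairs)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  degree <- tabulate(c(edges[, 1], edges[, 2]), nbins = tess$n)
  structure(list(n = tess$n, edges = edges, degree = degree,
                 boundary = boundary),
            class = "topological_graph")
}

#' @export
print.topological_graph <- function(x, ...) {
  cat(sprintf("topological_graph: %d points, %d Voronoi-adjacent pairs\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Voronoi polygon areas (domains of danger)
#'
#' Area of each agent's Voronoi polygon clipped to the chosen region.  Under
#' the selfish herd hypothesis an individual's cell area is its domain of
#' danger, the region of the plane whose nearest individual it is.  Areas
#' always sum to the area of the clipping region.
#'
#' @inheritParams voronoi_tessellation
#' @return Numeric vector of `P` areas.
#' @export
voronoi_areas <- function(positions, box = NULL, clip = c("box", "hull"),
                          inflate = 0) {
  voronoi_tessellation(positions, box = box, clip = match.arg(clip),
                       inflate = inflate)$areas
}
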