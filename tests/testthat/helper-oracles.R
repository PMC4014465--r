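# Independent brute-force oracles, deliberately naive implementations kept
# apart from the package code paths they verify.

# Exhaustive all-pairs sector nearest neighbour (closed sector, lowest index
# wins ties).
brute_sector_nn <- function(pos, i, gaze, alpha) {
  best <- NA_integer_
  bestd <- Inf
  for (k in seq_len(nrow(pos))) {
    if (k == i) next
    dx <- pos[k, 1] - pos[i, 1]; dy <- pos[k, 2] - pos[i, 2]
    d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    diff <- abs(((ang - gaze + pi) %% (2 * pi)) - pi)
    if (diff <= alpha / 2 && d < bestd) {
      bestd <- d
      best <- k
    }
  }
  best
}

# Union-find connected components of the closer-than-link graph.
brute_clusters <- function(pos, link) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < link) {
      ra <- find(i); rb <- find(j)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Length of the Voronoi edge shared by generators i and j inside a
# rectangular box, computed as a 1-D interval on the perpendicular
# bisector: every constraint |x - p_i| <= |x - p_k| and every box side is
# linear in the position along the bisector line.
bisector_edge_length <- function(pos, i, j, box) {
  pi_ <- pos[i, ]; pj <- pos[j, ]
  m <- (pi_ + pj) / 2
  dirv <- c(-(pj - pi_)[2], (pj - pi_)[1])
  dirv <- dirv / sqrt(sum(dirv^2))
  lo <- -Inf; hi <- Inf
  add <- function(a, b, lo, hi) {
    # constraint a * t <= b
    if (abs(a) < 1e-14) {
      if (b < 0) return(c(1, 0))   # infeasible
      return(c(lo, hi))
    }
    if (a > 0) c(lo, min(hi, b / a)) else c(max(lo, b / a), hi)
  }
  for (k in seq_len(nrow(pos))) {
    if (k == i || k == j) next
    # |m + t d - pi|^2 <= |m + t d - pk|^2  (linear in t)
    u <- pos[k, ] - pi_
    a <- 2 * sum(dirv * u)
    b <- sum((pos[k, ] - m)^2) - sum((pi_ - m)^2)
    r <- add(a, b, lo, hi); lo <- r[1]; hi <- r[2]
  }
  # box sides: xmin <= m1 + t d1 <= xmax etc.
  r <- add(dirv[1], box[2] - m[1], lo, hi); lo <- r[1]; hi <- r[2]
  r <- add(-dirv[1], m[1] - box[1], lo, hi); lo <- r[1]; hi <- r[2]
  r <- add(dirv[2], box[4] - m[2], lo, hi); lo <- r[1]; hi <- r[2]
  r <- add(-dirv[2], m[2] - box[3], lo, hi); lo <- r[1]; hi <- r[2]
  max(0, hi - lo)
}

# Full brute-force topological adjacency inside a box.
brute_adjacency <- function(pos, box, tol = 1e-8) {
  n <- nrow(pos)
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bisector_edge_length(pos, i, j, box) > tol)
      edges <- rbind(edges, c(i, j))
  }
  edges
}

rotate_points <- function(pos, angle, center = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(sweep(pos, 2, center) %*% t(R), 2, -center)
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}
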