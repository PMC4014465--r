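#' Simulation parameters
#'
#' Bundle and validate the constants of the attention-field swarm model.
#' The defaults are the typical values used throughout the model analysis:
#' a group of `P = 91` individuals in a box of side `L = 1.74` length units,
#' stress-zone radius (ideal inter-individual distance) `D = 0.1` and step
#' length `v = 0.0112` per time unit, which give an initial density of
#' about 30 individuals per unit area.
#'
#' @param P Number of agents (>= 1).
#' @param L Side of the square arena, length units.
#' @param D Stress-zone radius, length units.  Doubles as the ideal
#'   inter-individual distance: agents approach neighbours farther than `D`
#'   and retreat from neighbours closer than `D`.
#' @param v Step length per time unit (one time unit = one sweep of `P`
#'   asynchronous updates).
#' @param alpha Amplitude of the attention field, radians in `(0, 2*pi]`.
#'   The gaze direction drawn at each update bisects this angle;
#'   `alpha = 2*pi` reproduces Hamilton's move-to-nearest-neighbour rule.
#' @param eta Noise strength in `[0, 1]`: the movement direction is rotated
#'   by an angle uniform on `[-eta*pi, eta*pi]`.  `eta = 0` is noiseless,
#'   `eta = 1` a fully random direction.
#' @param qs_window Number of consecutive sweeps with no movement required
#'   to declare the quasi-stationary state.
#' @param max_sweeps Hard cap on the simulation length, sweeps.
#' @param seed Integer RNG seed used by [run_swarm()].
#' @param select Agent selection within a sweep: `"replacement"` (uniform
#'   random with replacement, `P` draws per time unit; the default protocol)
#'   or `"permutation"` (a fresh random permutation each sweep, kept for
#'   sensitivity checks).
#' @param dtol Dead band around `D` within which an agent does not move;
#'   keeps the quiescence detector well defined in floating point.
#'
#' @return An object of class `swarm_params` (a validated named list).
#' @examples
#' p <- swarm_params()
#' p$P * 1 / p$L^2  # nothing magic: density P / L^2
#' @export
swarm_params <- function(P = 91L, L = 1.74, D = 0.1, v = 0.0112,
                         alpha = pi / 2, eta = 0, qs_window = 100L,
                         max_sweeps = 60000L, seed = 1L,
                         select = c("replacement", "permutation"),
                         dtol = 1e-12) {
  select <- match.arg(select)
  p <- list(P = as.integer(P), L = as.numeric(L), D = as.numeric(D),
            v = as.numeric(v), alpha = as.numeric(alpha),
            eta = as.numeric(eta), qs_window = as.integer(qs_window),
            max_sweeps = as.integer(max_sweeps), seed = as.integer(seed),
            select = select, dtol = as.numeric(dtol))
  class(p) <- "swarm_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "swarm_params"))
  with(p, {
    if (P < 1L) stop("P must be >= 1")
    if (L <= 0) stop("L must be > 0")
    if (D <= 0) stop("D must be > 0")
    if (v <= 0) stop("v must be > 0")
    if (!(alpha > 0 && alpha <= 2 * pi)) stop("alpha must be in (0, 2*pi]")
    if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
    if (qs_window < 1L) stop("qs_window must be >= 1")
    if (max_sweeps < 1L) stop("max_sweeps must be >= 1")
    if (dtol < 0) stop("dtol must be >= 0")
  })
  invisible(p)
}

#' @export
print.swarm_params <- function(x, ...) {
  cat("Attention-field swarm parameters\n")
  cat(sprintf("  P = %d agents, box L = %g, density P/L^2 = %.3f\n",
              x$P, x$L, x$P / x$L^2))
  cat(sprintf("  D = %g, v = %g, alpha = %.4f rad (%.1f deg), eta = %g\n",
              x$D, x$v, x$alpha, x$alpha * 180 / pi, x$eta))
  cat(sprintf("  qs_window = %d, max_sweeps = %d, seed = %d, select = %s\n",
              x$qs_window, x$max_sweeps, x$seed, x$select))
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' The configuration format is one `key = value` pair per line (`#` starts a
#' comment).  Keys mirror the arguments of [swarm_params()]; missing keys
#' take the defaults, unknown keys are an error.
#'
#' @param path File path.
#' @param overrides Named list of values taking precedence over the file
#'   (mirrors command-line flags overriding a config file).
#' @return [read_swarm_config()] returns a `swarm_params`;
#'   [write_swarm_config()] invisibly returns `path`.
#' @export
read_swarm_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop("malformed config line: '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    kv[[key]] <- if (key == "select") val else as.numeric(val)
  }
  kv[names(overrides)] <- overrides
  allowed <- names(formals(swarm_params))
  bad <- setdiff(names(kv), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(swarm_params, kv)
}

#' @rdname read_swarm_config
#' @param params A `swarm_params` object.
#' @export
write_swarm_config <- function(params, path) {
  validate_params(params)
  vals <- vapply(params, function(v)
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v),
    character(1))
  writeLines(paste(names(params), vals, sep = " = "), path)
  invisible(path)
}
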