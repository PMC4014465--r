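#' Write a trajectory to CSV
#'
#' One row per sampled agent-state with columns `t,agent_id,x,y`;
#' coordinates are serialised with 17 significant digits so the write/read
#' round trip is lossless for doubles.  The parameters, seed and
#' convergence record go to a flat key-value sidecar file
#' (`<path>.meta` by default).
#'
#' @param traj A `swarm_trajectory` from [run_swarm()].
#' @param path Output CSV path.
#' @param meta_path Sidecar metadata path, or `NULL` to skip it.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, meta_path = paste0(path, ".meta")) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  rows <- do.call(rbind, lapply(seq_along(traj$ts), function(k) {
    p <- traj$samples[[k]]
    data.frame(t = traj$ts[k], agent_id = seq_len(nrow(p)),
               x = sprintf("%.17g", p[, 1]), y = sprintf("%.17g", p[, 2]))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- c(
      paste(names(traj$params)[1:9],
            vapply(traj$params[1:9], function(v) sprintf("%.17g", as.numeric(v)),
                   character(1)), sep = " = "),
      paste("select =", traj$params$select),
      sprintf("converged = %d", as.integer(traj$converged)),
      sprintf("t_conv = %s", ifelse(is.na(traj$t_conv), "NA", traj$t_conv)),
      sprintf("sweeps_run = %d", traj$sweeps_run),
      sprintf("clamp_events = %d", traj$clamp_events))
    writeLines(meta, meta_path)
  }
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Validates the file while parsing: the header must be exactly
#' `t,agent_id,x,y`, every field numeric, times non-decreasing and every
#' frame must contain the same agents; violations raise an error naming the
#' offending line.  An empty file is an error, not an empty trajectory.
#'
#' @param path CSV path written by [write_trajectory()].
#' @param meta_path Sidecar path; if the file exists the parameters and
#'   convergence record are restored, otherwise they are `NA`.
#' @return A `swarm_trajectory` (with `params = NULL` when no sidecar).
#' @export
read_trajectory <- function(path, meta_path = paste0(path, ".meta")) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty trajectory file: ", path)
  if (trimws(lines[1]) != "t,agent_id,x,y")
    stop("line 1: expected header 't,agent_id,x,y', got '", lines[1], "'")
  if (length(lines) < 2L) stop("trajectory has a header but no rows")
  body <- lines[-1]
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("line ", which(nf != 4L)[1] + 1L, ": expected 4 fields, found ",
         nf[nf != 4L][1])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 4L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1]
    stop("line ", bad + 1L, ": non-numeric field in '", body[bad], "'")
  }
  ts <- m[, 1]
  if (is.unsorted(ts)) stop("frame times are not non-decreasing")
  uts <- unique(ts)
  P <- sum(ts == uts[1])
  samples <- vector("list", length(uts))
  for (k in seq_along(uts)) {
    rows <- which(ts == uts[k])
    if (length(rows) != P)
      stop("frame t = ", uts[k], ": expected ", P, " agents, found ",
           length(rows), " (near line ", rows[1] + 1L, ")")
    ids <- m[rows, 2]
    if (!setequal(ids, seq_len(P)))
      stop("frame t = ", uts[k], ": agent ids are not 1..", P)
    samples[[k]] <- m[rows, 3:4, drop = FALSE][order(ids), , drop = FALSE]
  }
  params <- NULL; converged <- NA; t_conv <- NA_integer_
  sweeps_run <- as.integer(uts[length(uts)]); clamps <- NA_integer_
  if (!is.null(meta_path) && file.exists(meta_path)) {
    kv <- read_kv(meta_path)
    pnames <- setdiff(names(formals(swarm_params)), "select")
    pk <- intersect(names(kv), pnames)
    params <- do.call(swarm_params,
                      c(lapply(kv[pk], as.numeric),
                        list(select = kv[["select"]])))
    converged <- as.logical(as.integer(kv[["converged"]]))
    t_conv <- suppressWarnings(as.integer(kv[["t_conv"]]))
    sweeps_run <- as.integer(as.numeric(kv[["sweeps_run"]]))
    clamps <- as.integer(as.numeric(kv[["clamp_events"]]))
  }
  structure(list(params = params,
                 seed = if (is.null(params)) NA_integer_ else params$seed,
                 ts = as.integer(uts), samples = samples,
                 converged = converged, t_conv = t_conv,
                 sweeps_run = sweeps_run, clamp_events = clamps,
                 moved_counts = NULL),
            class = "swarm_trajectory")
}

read_kv <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed metadata line ", bad[1])
  setNames(vapply(parts, `[`, character(1), 3L),
           vapply(parts, `[`, character(1), 2L))
}

#' Write a metrics table to CSV
#'
#' @param metrics A `data.frame` of metric records (for example rows from
#'   [swarm_metrics()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
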