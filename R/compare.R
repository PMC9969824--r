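# Multi-simulation synchronization: align trajectories on a shared frame
# axis so events (a substance entering the membrane, different output
# intervals) line up. Aligned index k maps to local frame offset + k*stride
# in each trajectory; positions outside a trajectory's range are missing.

#' Per-trajectory synchronization parameters
#'
#' @param offsets Integer frame offsets, one per trajectory (may be
#'   negative).
#' @param strides Integer strides >= 1, one per trajectory (recycled).
#' @return A `sync_spec`.
#' @export
sync_spec <- function(offsets = 0L, strides = 1L) {
  offsets <- as.integer(offsets)
  strides <- as.integer(rep_len(strides, length(offsets)))
  if (any(is.na(offsets))) stop2("offsets must be integers")
  if (any(is.na(strides)) || any(strides < 1L))
    stop2("strides must be integers >= 1")
  structure(list(offsets = offsets, strides = strides), class = "sync_spec")
}

#' Align trajectories on a shared frame axis
#'
#' @param lengths Integer frame counts, one per trajectory.
#' @param spec A [sync_spec()] with matching length.
#' @return Integer matrix `K x n_traj` of local frame indices (0-based),
#'   `NA` where a trajectory has no frame at that aligned position. `K` is
#'   the last aligned index at which at least one trajectory is still valid.
#' @export
synchronize <- function(lengths, spec) {
  stopifnot(inherits(spec, "sync_spec"))
  lengths <- as.integer(lengths)
  if (any(is.na(lengths)) || any(lengths < 1L))
    stop2("trajectory lengths must be >= 1")
  nt <- length(lengths)
  if (length(spec$offsets) != nt)
    stop2("sync_spec covers ", length(spec$offsets), " trajectories, got ",
          nt, " lengths")
  # largest k with offset + k*stride <= length-1, per trajectory
  kmax <- floor((lengths - 1L - spec$offsets) / spec$strides)
  K <- max(kmax) + 1L
  if (K < 1L) stop2("no aligned frames: all offsets beyond trajectory ends")
  tab <- matrix(NA_integer_, K, nt)
  for (j in seq_len(nt)) {
    k <- 0:(K - 1L)
    local <- spec$offsets[[j]] + k * spec$strides[[j]]
    ok <- local >= 0L & local < lengths[[j]]
    tab[ok, j] <- local[ok]
  }
  colnames(tab) <- paste0("traj", seq_len(nt))
  tab
}

#' Combine per-trajectory series on an aligned axis
#'
#' @param series_per_traj List of data frames, one per trajectory; each must
#'   be indexed by its local frames (row i = local frame i-1). The first
#'   column is taken as the local x axis and dropped; the first data column
#'   is used.
#' @param alignment Matrix from [synchronize()].
#' @param labels Column labels (default trajectory names); name collisions
#'   are resolved by suffixing the trajectory number.
#' @return Data frame `aligned` (0-based aligned index) plus one column per
#'   trajectory, `NA` where the alignment has no frame.
#' @export
series_compare <- function(series_per_traj, alignment, labels = NULL) {
  nt <- ncol(alignment)
  if (length(series_per_traj) != nt)
    stop2("need one series per trajectory (", nt, ")")
  labels <- labels %||% vapply(seq_len(nt), function(j) {
    nm <- names(series_per_traj[[j]])
    if (length(nm) >= 2L) nm[[2]] else paste0("traj", j)
  }, character(1))
  labels <- as.character(labels)
  dup <- duplicated(labels)
  labels[dup] <- paste0(labels[dup], "_", which(dup))
  out <- data.frame(aligned = seq_len(nrow(alignment)) - 1L)
  for (j in seq_len(nt)) {
    vals <- as.numeric(series_per_traj[[j]][[2]])
    local <- alignment[, j]
    col <- rep(NA_real_, nrow(alignment))
    ok <- !is.na(local) & local + 1L <= length(vals)
    col[ok] <- vals[local[ok] + 1L]
    out[[labels[[j]]]] <- col
  }
  attr(out, "xlabel") <- "aligned frame"
  attr(out, "ylabel") <- attr(series_per_traj[[1]], "ylabel") %||% "value"
  out
}

#' Convert a time offset (ps) to the nearest frame offset
#'
#' Convenience for time-based alignment: divides by the frame interval and
#' rounds half-down to an integer frame offset.
#'
#' @param time_ps Offset in ps.
#' @param dt_ps Trajectory output interval in ps.
#' @return Integer frame offset.
#' @export
time_to_frame_offset <- function(time_ps, dt_ps) {
  if (dt_ps <= 0) stop2("'dt_ps' must be positive")
  as.integer(ceiling(time_ps / dt_ps - 0.5))
}
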