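#' Select a frame window and stride
#'
#' @param first First frame, 0-based, inclusive.
#' @param last Last frame, 0-based, inclusive; `NULL` means end of file.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @return A `frame_range` object. With an explicit `last`, the number of
#'   frames yielded is `floor((last - first) / stride) + 1`.
#' @export
frame_range <- function(first = 0L, last = NULL, stride = 1L) {
  if (!is_count(first) || first < 0) stop2("'first' must be a >= 0 integer")
  if (!is.null(last)) {
    if (!is_count(last) || last < first)
      stop2("'last' must be an integer >= 'first'")
    last <- as.integer(last)
  }
  if (!is_count(stride) || stride < 1) stop2("'stride' must be >= 1")
  structure(list(first = as.integer(first), last = last,
                 stride = as.integer(stride)),
            class = "frame_range")
}

# Local (0-based) frame indices selected by a range in a file of n frames.
.range_indices <- function(range, n_frames) {
  last <- min(range$last %||% (n_frames - 1L), n_frames - 1L)
  if (range$first > last) return(integer())
  seq.int(range$first, last, by = range$stride)
}

.traj_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("xtc", "trr"))
    stop2("unsupported trajectory format '.", ext, "' (XTC or TRR)")
  ext
}

.check_box <- function(boxmat, what) {
  off <- boxmat[row(boxmat) != col(boxmat)]
  if (any(abs(off) > 1e-6))
    stop2("triclinic box in ", what, " is not supported (flat orthorhombic ",
          "membranes only)")
  d <- diag(boxmat)
  if (any(!is.finite(d)) || any(d <= 0)) stop2("invalid box in ", what)
  d
}

#' Open a trajectory for streaming access
#'
#' Returns a lightweight reader holding only file metadata; frames are read
#' one at a time with [next_frame()], so memory use is a single frame
#' regardless of trajectory length.
#'
#' @param traj_path XTC or TRR file.
#' @param topology The matching `membrane_topology` (atom counts must agree).
#' @param range A [frame_range()].
#' @return A `trajectory_reader`.
#' @export
open_trajectory <- function(traj_path, topology, range = frame_range()) {
  if (!file.exists(traj_path)) stop2("trajectory not found: ", traj_path)
  stopifnot(inherits(topology, "membrane_topology"),
            inherits(range, "frame_range"))
  fmt <- .traj_format(traj_path)
  env <- new.env(parent = emptyenv())
  if (fmt == "xtc") {
    scan <- .Call(C_xtc_scan, traj_path)
    env$read1 <- function(i) {
      fr <- .Call(C_xtc_read_frame, traj_path, scan$offset[[i]])
      box <- .check_box(matrix(fr$box, 3, 3, byrow = TRUE), traj_path)
      frame_data(fr$coords, box, time = fr$time, frame_index = i - 1L)
    }
    env$n_total <- length(scan$offset)
    natoms_file <- scan$natoms
  } else {
    scan <- .trr_scan(traj_path)
    env$read1 <- function(i) {
      fr <- .trr_read_frame(scan, i)
      if (is.null(fr$coords)) stop2("TRR frame ", i - 1L, " has no coordinates")
      box <- .check_box(fr$box, traj_path)
      frame_data(fr$coords, box, time = fr$time, frame_index = i - 1L)
    }
    env$n_total <- length(scan$offset)
    natoms_file <- scan$natoms
  }
  if (env$n_total == 0L) stop2("no complete frames in '", traj_path, "'")
  if (!is.na(natoms_file) && natoms_file != topology$natoms)
    stop2("atom count mismatch: trajectory has ", natoms_file,
          ", topology has ", topology$natoms)
  env$sel <- .range_indices(range, env$n_total)
  env$cursor <- 0L
  env$n_reads <- 0L
  structure(list(path = traj_path, format = fmt, env = env, range = range),
            class = "trajectory_reader")
}

#' Number of frames a reader will yield
#' @param reader A `trajectory_reader`.
#' @return Integer.
#' @export
n_frames <- function(reader) length(reader$env$sel)

#' Read the next selected frame
#'
#' @param reader A `trajectory_reader`.
#' @return A `frame_data`, or `NULL` when the selection is exhausted. The
#'   `frame_index` is the 0-based index in the file (not in the selection).
#' @export
next_frame <- function(reader) {
  env <- reader$env
  if (env$cursor >= length(env$sel)) return(NULL)
  env$cursor <- env$cursor + 1L
  env$n_reads <- env$n_reads + 1L
  env$read1(env$sel[[env$cursor]] + 1L)
}

#' Rewind a reader to the start of its selection
#' @param reader A `trajectory_reader`.
#' @return The reader, invisibly.
#' @export
rewind <- function(reader) {
  reader$env$cursor <- 0L
  invisible(reader)
}

# frames decoded so far (streaming-contract instrumentation)
reader_read_count <- function(reader) reader$env$n_reads

#' Read trajectory frames
#'
#' Streaming wrapper around [open_trajectory()]/[next_frame()]. With a
#' `callback`, each frame is passed to it and discarded (one frame in memory
#' at a time); without one, all selected frames are returned as a list.
#'
#' @param traj_path XTC or TRR file.
#' @param topology The matching `membrane_topology`.
#' @param range A [frame_range()].
#' @param callback Optional `function(frame)`.
#' @return List of `frame_data` (no callback) or the callback results,
#'   invisibly.
#' @export
read_trajectory <- function(traj_path, topology, range = frame_range(),
                            callback = NULL) {
  reader <- open_trajectory(traj_path, topology, range)
  out <- vector("list", n_frames(reader))
  k <- 0L
  while (!is.null(fr <- next_frame(reader))) {
    k <- k + 1L
    out[[k]] <- if (is.null(callback)) fr else callback(fr)
  }
  if (is.null(callback)) out else invisible(out)
}

#' Append a frame to an XTC trajectory
#'
#' @param path Output file.
#' @param coords `natoms x 3` matrix, nm.
#' @param box Length-3 `(lx, ly, lz)` nm.
#' @param step Integer MD step.
#' @param time Time, ps.
#' @param precision XTC coordinate quantum is `1/precision` nm (default 1000,
#'   i.e. coordinates are stored to 0.001 nm).
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
write_xtc_frame <- function(path, coords, box, step = 0L, time = 0,
                            precision = 1000, append = FALSE) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  boxm <- diag(as.numeric(box))
  .Call(C_xtc_write_frame, path, coords, as.double(t(boxm)),
        as.integer(step), as.double(time), as.double(precision),
        isTRUE(append))
  invisible(path)
}
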