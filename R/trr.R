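# GROMACS TRR reader/writer in plain R. TRR is straight big-endian XDR:
# per frame a header (magic 1993, the "GMX_trn_file" tag, ten section byte
# counts, natoms/step/nre, time and lambda) followed by box, virial,
# pressure, coordinate, velocity and force blocks, each either single or
# double precision. Precision is inferred from the box (or x) byte count.

.TRR_MAGIC <- 1993L
.TRR_TAG <- "GMX_trn_file"

.trr_read_header <- function(raw, pos) {
  rd_i <- function(p) readBin(raw[p:(p + 3L)], "integer", 1L, size = 4L,
                              endian = "big")
  if (pos + 3L > length(raw)) return(NULL)
  magic <- rd_i(pos)
  if (magic != .TRR_MAGIC)
    stop2("bad TRR magic (", magic, ") at byte ", pos - 1L)
  slen <- rd_i(pos + 4L)
  strlen <- rd_i(pos + 8L)
  tag <- rawToChar(raw[(pos + 12L):(pos + 11L + strlen)])
  if (tag != .TRR_TAG) stop2("unexpected TRR version tag '", tag, "'")
  p <- pos + 12L + strlen + (4L - strlen %% 4L) %% 4L
  ints <- vapply(0:12, function(k) rd_i(p + 4L * k), integer(1))
  names(ints) <- c("ir", "e", "box", "vir", "pres", "top", "sym",
                   "x", "v", "f", "natoms", "step", "nre")
  p <- p + 52L
  natoms <- ints[["natoms"]]
  prec <- if (ints[["box"]] > 0) ints[["box"]] %/% 9L
          else if (ints[["x"]] > 0) ints[["x"]] %/% (3L * natoms)
          else 4L
  if (!prec %in% c(4L, 8L)) stop2("cannot infer TRR precision")
  rd_f <- function(p) readBin(raw[p:(p + prec - 1L)], "double", 1L,
                              size = prec, endian = "big")
  tm <- rd_f(p)
  lambda <- rd_f(p + prec)
  p <- p + 2L * prec
  list(sizes = ints, natoms = natoms, step = ints[["step"]], time = tm,
       lambda = lambda, prec = prec, data_pos = p)
}

# Scan all frame offsets. Returns list(natoms, step, time, offset, prec).
.trr_scan <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  pos <- 1L
  out <- list(step = numeric(), time = numeric(), offset = numeric())
  natoms <- NA_integer_
  prec <- NA_integer_
  while (pos <= length(raw)) {
    h <- tryCatch(.trr_read_header(raw, pos), error = function(e) stop2(
      conditionMessage(e), " in '", path, "'"))
    if (is.null(h)) break
    if (is.na(natoms)) natoms <- h$natoms
    else if (natoms != h$natoms) stop2("inconsistent atom count in '", path, "'")
    prec <- h$prec
    datalen <- sum(h$sizes[c("box", "vir", "pres", "x", "v", "f")])
    nxt <- h$data_pos + datalen
    if (nxt - 1L > length(raw)) {
      warning("truncated final TRR frame in '", path, "' ignored",
              call. = FALSE)
      break
    }
    out$step <- c(out$step, h$step)
    out$time <- c(out$time, h$time)
    out$offset <- c(out$offset, pos)
    pos <- nxt
  }
  c(list(natoms = natoms, prec = prec), out, list(raw = raw))
}

# Read one frame given a scan result and its index.
.trr_read_frame <- function(scan, i) {
  h <- .trr_read_header(scan$raw, as.integer(scan$offset[[i]]))
  prec <- h$prec
  p <- h$data_pos
  rd_vec <- function(p, n) readBin(scan$raw[p:(p + n * prec - 1L)], "double",
                                   n, size = prec, endian = "big")
  box <- NULL
  if (h$sizes[["box"]] > 0) {
    box <- matrix(rd_vec(p, 9L), 3, 3, byrow = TRUE)
    p <- p + h$sizes[["box"]]
  }
  p <- p + h$sizes[["vir"]] + h$sizes[["pres"]]
  coords <- NULL
  if (h$sizes[["x"]] > 0) {
    coords <- matrix(rd_vec(p, 3L * h$natoms), ncol = 3, byrow = TRUE)
  }
  list(natoms = h$natoms, step = h$step, time = h$time, box = box,
       coords = coords, prec = prec)
}

#' Append a frame to a TRR trajectory
#'
#' Writes a coordinate-only TRR frame (no velocities/forces). With
#' `double_precision = TRUE` coordinates survive a round trip bit-faithfully.
#'
#' @param path Output file.
#' @param coords `natoms x 3` matrix, nm.
#' @param box Length-3 `(lx, ly, lz)` nm (orthorhombic).
#' @param step Integer MD step.
#' @param time Time in ps.
#' @param lambda Coupling parameter slot (default 0).
#' @param double_precision Write doubles (default) or single floats.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
write_trr_frame <- function(path, coords, box, step = 0L, time = 0,
                            lambda = 0, double_precision = TRUE,
                            append = FALSE) {
  coords <- as.matrix(coords)
  natoms <- nrow(coords)
  prec <- if (double_precision) 8L else 4L
  con <- file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "big")
  wf <- function(v) writeBin(as.double(v), con, size = prec, endian = "big")
  wi(.TRR_MAGIC)
  wi(13L)  # strlen + 1, as GROMACS writes it
  wi(nchar(.TRR_TAG))
  writeBin(charToRaw(.TRR_TAG), con)
  sizes <- c(ir = 0L, e = 0L, box = 9L * prec, vir = 0L, pres = 0L,
             top = 0L, sym = 0L, x = 3L * natoms * prec, v = 0L, f = 0L)
  wi(sizes)
  wi(natoms)
  wi(step)
  wi(0L)  # nre
  wf(time)
  wf(lambda)
  boxm <- diag(as.numeric(box))
  wf(as.vector(t(boxm)))
  wf(as.vector(t(coords)))
  invisible(path)
}
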