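#' Read a PDB topology and resolve lipids
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) and resolves every residue
#' matching one of the supplied lipid definitions into a lipid with one head
#' (key) atom and zero or more tail atoms. The topology carries structure
#' only; the PDB coordinates are kept separately as a reference frame
#' (Angstrom converted to nm) retrievable with [reference_frame()].
#'
#' @param pdb_path Path to a PDB file.
#' @param lipid_defs List of [lipid_def()] objects; defaults to
#'   [default_lipid_defs()].
#' @return An object of class `membrane_topology` with elements `atoms`
#'   (data frame: `atom_name`, `resname`, `resid`, `chain`), `natoms`,
#'   `lipids` (data frame: `lipid_id`, `resname`, `resid`, `head` atom index,
#'   list column `tails`), and `lipid_defs`.
#' @details A residue matching a definition but lacking the head atom is an
#'   error (the tessellation would silently lose that lipid otherwise). A
#'   topology with zero lipids is allowed with a warning.
#' @export
read_topology <- function(pdb_path, lipid_defs = default_lipid_defs()) {
  if (!file.exists(pdb_path)) stop2("PDB file not found: ", pdb_path)
  if (inherits(lipid_defs, "lipid_def")) lipid_defs <- list(lipid_defs)
  stopifnot(all(vapply(lipid_defs, inherits, logical(1), "lipid_def")))

  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e) stop2("cannot parse '", pdb_path,
                                            "': ", conditionMessage(e)))
  at <- pdb$atom
  atoms <- data.frame(atom_name = trimws(at$elety),
                      resname = trimws(at$resid),
                      resid = at$resno,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      stringsAsFactors = FALSE)
  natoms <- nrow(atoms)
  if (natoms == 0L) stop2("no ATOM/HETATM records in '", pdb_path, "'")

  box <- .read_cryst1(pdb_path)
  coords <- cbind(at$x, at$y, at$z) * .NM_PER_ANGSTROM

  defs_by_res <- setNames(lipid_defs,
                          vapply(lipid_defs, `[[`, character(1), "resname"))
  # residues = runs of constant (chain, resid, resname)
  key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "\r")
  res_start <- which(key != c("", key[-natoms]))
  res_end <- c(res_start[-1] - 1L, natoms)

  lipid_rows <- list()
  for (r in seq_along(res_start)) {
    idx <- res_start[[r]]:res_end[[r]]
    rn <- atoms$resname[[res_start[[r]]]]
    def <- defs_by_res[[rn]]
    if (is.null(def)) next
    head_idx <- idx[atoms$atom_name[idx] == def$head_atom]
    if (length(head_idx) != 1L)
      stop2("residue ", rn, " ", atoms$resid[[res_start[[r]]]],
            " matches lipid definition '", rn, "' but has ",
            length(head_idx), " atoms named '", def$head_atom,
            "' (need exactly one head atom)")
    tail_idx <- idx[atoms$atom_name[idx] %in% def$tail_atoms]
    lipid_rows[[length(lipid_rows) + 1L]] <-
      list(resname = rn, resid = atoms$resid[[res_start[[r]]]],
           head = head_idx, tails = tail_idx, res = r)
  }
  if (length(lipid_rows) == 0L)
    warning("no residues matched any lipid definition; topology has 0 lipids",
            call. = FALSE)
  lipids <- data.frame(
    lipid_id = seq_along(lipid_rows),
    resname = vapply(lipid_rows, `[[`, character(1), "resname"),
    resid = vapply(lipid_rows, `[[`, integer(1), "resid"),
    head = vapply(lipid_rows, `[[`, integer(1), "head"),
    stringsAsFactors = FALSE)
  lipids$tails <- lapply(lipid_rows, `[[`, "tails")

  # membership of every atom in a lipid residue (NA = non-lipid, e.g. protein)
  atoms$lipid_id <- NA_integer_
  for (k in seq_along(lipid_rows)) {
    rr <- lipid_rows[[k]]$res
    atoms$lipid_id[res_start[[rr]]:res_end[[rr]]] <- k
  }

  structure(list(atoms = atoms, natoms = natoms, lipids = lipids,
                 lipid_defs = lipid_defs,
                 ref_coords = coords, ref_box = box, source = pdb_path),
            class = "membrane_topology")
}

.read_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(ln) == 0L) return(NULL)
  ln <- ln[[1]]
  abc <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                      substr(ln, 25, 33)))
  ang <- as.numeric(c(substr(ln, 34, 40), substr(ln, 41, 47),
                      substr(ln, 48, 54)))
  if (any(is.na(abc))) return(NULL)
  if (any(!is.na(ang)) && any(abs(ang - 90) > 1e-6))
    stop2("non-orthorhombic CRYST1 box (angles ", paste(ang, collapse = ", "),
          "); only orthorhombic boxes are supported")
  abc * .NM_PER_ANGSTROM
}

#' @export
print.membrane_topology <- function(x, ...) {
  cat(sprintf("<membrane_topology> %d atoms, %d lipids (%s)\n", x$natoms,
              nrow(x$lipids),
              paste(names(sort(table(x$lipids$resname), decreasing = TRUE)),
                    collapse = ", ")))
  if (!is.null(x$ref_box))
    cat(sprintf("  reference box: %.3f x %.3f x %.3f nm\n",
                x$ref_box[1], x$ref_box[2], x$ref_box[3]))
  invisible(x)
}

#' Number of lipids in a topology
#' @param topology A `membrane_topology`.
#' @return Integer count.
#' @export
n_lipids <- function(topology) nrow(topology$lipids)

#' Reference frame from the topology's PDB coordinates
#'
#' @param topology A `membrane_topology`.
#' @return A `frame_data` with coordinates in nm and the CRYST1 box (if
#'   present; otherwise a loose bounding box with a warning).
#' @export
reference_frame <- function(topology) {
  box <- topology$ref_box
  if (is.null(box)) {
    warning("PDB had no CRYST1 record; using bounding box of coordinates",
            call. = FALSE)
    box <- apply(topology$ref_coords, 2, function(v) diff(range(v))) + 1e-6
  }
  frame_data(topology$ref_coords, box, time = 0, frame_index = 0L)
}

#' Construct per-frame data
#'
#' @param coords Numeric matrix `natoms x 3`, nm.
#' @param box Numeric length-3 `(lx, ly, lz)`, nm, orthorhombic.
#' @param time Time in ps.
#' @param frame_index 0-based frame index within its trajectory.
#' @return An object of class `frame_data`.
#' @export
frame_data <- function(coords, box, time = 0, frame_index = 0L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop2("'coords' must be an n x 3 matrix")
  if (!all(is.finite(coords))) stop2("non-finite coordinates in frame")
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop2("'box' must be three positive box lengths (lx, ly, lz)")
  structure(list(coords = coords, box = box, time = as.numeric(time),
                 frame_index = as.integer(frame_index)),
            class = "frame_data")
}

#' @export
print.frame_data <- function(x, ...) {
  cat(sprintf("<frame_data> frame %d, t = %g ps, %d atoms, box %.3f x %.3f x %.3f nm\n",
              x$frame_index, x$time, nrow(x$coords), x$box[1], x$box[2],
              x$box[3]))
  invisible(x)
}

# Fixed-column PDB writer used by the synthetic generator; sprintf only so
# output bytes are reproducible.
write_pdb_file <- function(path, atom_names, resnames, resids, coords_nm,
                           box_nm) {
  xyz <- coords_nm / .NM_PER_ANGSTROM
  con <- file(path, "wb")  # binary: fixed '\n', identical bytes everywhere
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl("REMARK    synthetic bilayer written by lipidvoro")
  wl(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
             box_nm[1] * 10, box_nm[2] * 10, box_nm[3] * 10, 90, 90, 90))
  nm4 <- ifelse(nchar(atom_names) < 4L, sprintf(" %-3s", atom_names),
                substr(atom_names, 1, 4))
  wl(sprintf("ATOM  %5d %4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f",
             seq_along(atom_names) %% 100000L, nm4, resnames,
             resids %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0))
  wl("END")
  invisible(path)
}
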