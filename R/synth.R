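# Synthetic bilayer generator.
#
# Produces minimal but structurally complete bilayers with known ground
# truth, written in the same formats the readers consume (PDB + XTC/TRR +
# NDX + truth TSV), so the whole pipeline runs without external data. Each
# lipid is three atoms: head "P" at the leaflet surface and two tail carbons
# "C2"/"C3" at 0.5 and 1.0 nm toward the midplane (inverted lipids point
# their tails outward instead, keeping the head in place). Randomness uses
# R's Mersenne-Twister seeded from spec$seed; the caller's RNG state is
# saved and restored, and a fixed seed reproduces output files byte for
# byte.

#' Describe a synthetic bilayer
#'
#' @param nx,ny Lipids per leaflet along x and y (lattice).
#' @param spacing Lattice spacing, nm (APL of the perfect lattice is
#'   `spacing^2`).
#' @param thickness Head-to-head bilayer thickness, nm.
#' @param jitter_xy,jitter_z Gaussian positional noise sigma, nm.
#' @param curvature `"none"` or `"quad_bulge"` (a paraboloid cap of total
#'   polynomial degree 2, so a degree-2 midsurface fit recovers it exactly).
#' @param curvature_amplitude Bulge height at the box center, nm.
#' @param inverted_fraction Fraction of lipids per leaflet with head/tail
#'   orientation inverted (tails pointing outward); chosen by a seeded
#'   shuffle, exactly `round(fraction * n)` per leaflet.
#' @param inclusion `NULL` or `list(radius =, n_atoms =)`: a cylinder of
#'   non-lipid atoms (resname PROT) spanning the bilayer at the box center.
#' @param n_frames Number of trajectory frames (jitter regenerated per
#'   frame).
#' @param seed RNG seed.
#' @param resname Lipid residue name.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(nx = 8L, ny = 8L, spacing = 0.8, thickness = 4,
                       jitter_xy = 0, jitter_z = 0,
                       curvature = c("none", "quad_bulge"),
                       curvature_amplitude = 0, inverted_fraction = 0,
                       inclusion = NULL, n_frames = 1L, seed = 1L,
                       resname = "DPPC") {
  curvature <- match.arg(curvature)
  if (nx * ny < 4L) stop2("need at least 4 lipids per leaflet (nx*ny >= 4)")
  if (spacing <= 0 || thickness <= 0) stop2("spacing and thickness must be > 0")
  if (inverted_fraction < 0 || inverted_fraction > 1)
    stop2("'inverted_fraction' must be in [0, 1]")
  if (!is.null(inclusion)) {
    stopifnot(is.list(inclusion), all(c("radius", "n_atoms") %in%
                                        names(inclusion)))
    if (2 * inclusion$radius >= min(nx, ny) * spacing)
      stop2("box too small for inclusion radius ", inclusion$radius, " nm")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
                 thickness = thickness, jitter_xy = jitter_xy,
                 jitter_z = jitter_z, curvature = curvature,
                 curvature_amplitude = curvature_amplitude,
                 inverted_fraction = inverted_fraction,
                 inclusion = inclusion, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), resname = resname),
            class = "synth_spec")
}

.curv_offset <- function(spec, x, y, lx, ly) {
  if (spec$curvature == "none" || spec$curvature_amplitude == 0)
    return(rep(0, length(x)))
  # paraboloid cap, total degree 2: amp * (1 - ((2x/lx-1)^2 + (2y/ly-1)^2)/2)
  u <- 2 * x / lx - 1
  v <- 2 * y / ly - 1
  spec$curvature_amplitude * (1 - (u^2 + v^2) / 2)
}

# One frame's coordinates (natoms x 3). Atom order: all lipids (upper then
# lower, row-major lattice; P, C2, C3 each), then inclusion atoms.
.synth_coords <- function(spec, layout) {
  lx <- layout$box[[1]]; ly <- layout$box[[2]]
  n_per <- spec$nx * spec$ny
  hx <- rep(layout$lat_x, 2) + rnorm(2 * n_per, 0, spec$jitter_xy)
  hy <- rep(layout$lat_y, 2) + rnorm(2 * n_per, 0, spec$jitter_xy)
  zsign <- rep(c(1, -1), each = n_per)  # upper then lower
  curv <- .curv_offset(spec, rep(layout$lat_x, 2), rep(layout$lat_y, 2),
                       lx, ly)
  hz <- layout$zmid + zsign * spec$thickness / 2 + curv +
    rnorm(2 * n_per, 0, spec$jitter_z)
  # tails: toward midplane for normal lipids, outward for inverted
  tail_dir <- -zsign
  tail_dir[layout$inverted] <- zsign[layout$inverted]
  coords <- matrix(NA_real_, layout$natoms, 3)
  li <- seq_len(2 * n_per)
  coords[3 * (li - 1) + 1, ] <- cbind(hx, hy, hz)
  coords[3 * (li - 1) + 2, ] <- cbind(hx, hy, hz + 0.5 * tail_dir)
  coords[3 * (li - 1) + 3, ] <- cbind(hx, hy, hz + 1.0 * tail_dir)
  if (!is.null(spec$inclusion))
    coords[3 * 2 * n_per + seq_len(spec$inclusion$n_atoms), ] <- layout$inc_xyz
  coords
}

#' Generate a synthetic bilayer (PDB + trajectory + NDX + ground truth)
#'
#' Writes `<prefix>.pdb`, `<prefix>.xtc` (or `.trr`), `<prefix>.ndx` (group
#' `heads` with the key-atom indices) and `<prefix>_truth.tsv` with the
#' per-lipid ground-truth leaflet label and inverted flag. The same seed
#' produces byte-identical files.
#'
#' @param spec A [synth_spec()].
#' @param out_prefix Path prefix for the output files.
#' @param traj_format `"xtc"` (default) or `"trr"`.
#' @param xtc_precision XTC quantization (default 10000, i.e. 1e-4 nm, so
#'   lattice geometry survives the round trip well below metric tolerances).
#' @return List with file `paths`, the `truth` data frame, `box` and the
#'   spec, invisibly.
#' @export
generate_bilayer <- function(spec, out_prefix, traj_format = c("xtc", "trr"),
                             xtc_precision = 10000) {
  stopifnot(inherits(spec, "synth_spec"))
  traj_format <- match.arg(traj_format)
  # seed locally; restore the caller's RNG state on exit
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  n_per <- spec$nx * spec$ny
  lx <- spec$nx * spec$spacing
  ly <- spec$ny * spec$spacing
  amp <- if (spec$curvature == "quad_bulge") spec$curvature_amplitude else 0
  lz <- 2 * spec$thickness + 2 * abs(amp) + 2
  zmid <- lz / 2
  lat <- expand.grid(ix = seq_len(spec$nx) - 1L, iy = seq_len(spec$ny) - 1L)
  lat_x <- (lat$ix + 0.5) * spec$spacing
  lat_y <- (lat$iy + 0.5) * spec$spacing

  n_inv <- round(spec$inverted_fraction * n_per)
  inverted <- rep(FALSE, 2 * n_per)
  if (n_inv > 0) {
    inverted[sample.int(n_per, n_inv)] <- TRUE                # upper leaflet
    inverted[n_per + sample.int(n_per, n_inv)] <- TRUE        # lower leaflet
  }

  n_inc <- if (!is.null(spec$inclusion)) spec$inclusion$n_atoms else 0L
  inc_xyz <- NULL
  if (n_inc > 0) {
    # helix spanning the bilayer (plus 0.4 nm beyond each head plane)
    zspan <- c(zmid - spec$thickness / 2 - 0.4, zmid + spec$thickness / 2 + 0.4)
    ang <- 2 * pi * 0.618034 * seq_len(n_inc)
    rr <- spec$inclusion$radius * 0.8
    inc_xyz <- cbind(lx / 2 + rr * cos(ang), ly / 2 + rr * sin(ang),
                     seq(zspan[[1]], zspan[[2]], length.out = max(n_inc, 2L))[seq_len(n_inc)])
  }

  natoms <- 3L * 2L * n_per + n_inc
  layout <- list(box = c(lx, ly, lz), zmid = zmid, lat_x = lat_x,
                 lat_y = lat_y, inverted = inverted, inc_xyz = inc_xyz,
                 natoms = natoms)

  # topology tables
  li <- seq_len(2 * n_per)
  atom_names <- c(rep(c("P", "C2", "C3"), 2 * n_per),
                  rep("CA", n_inc))
  resnames <- c(rep(spec$resname, each = 3)[rep(seq_len(3), 2 * n_per)],
                rep("PROT", n_inc))
  resnames[seq_len(6 * n_per)] <- rep(spec$resname, 6 * n_per)
  resids <- c(rep(li, each = 3L), rep(2L * n_per + 1L, n_inc))

  paths <- list(pdb = paste0(out_prefix, ".pdb"),
                traj = paste0(out_prefix, ".", traj_format),
                ndx = paste0(out_prefix, ".ndx"),
                truth = paste0(out_prefix, "_truth.tsv"))

  coords0 <- .synth_coords(spec, layout)
  write_pdb_file(paths$pdb, atom_names, resnames, resids, coords0,
                 layout$box)
  for (f in seq_len(spec$n_frames)) {
    coords <- if (f == 1L) coords0 else .synth_coords(spec, layout)
    if (traj_format == "xtc") {
      write_xtc_frame(paths$traj, coords, layout$box, step = f - 1L,
                      time = f - 1, precision = xtc_precision,
                      append = f > 1L)
    } else {
      write_trr_frame(paths$traj, coords, layout$box, step = f - 1L,
                      time = f - 1, append = f > 1L)
    }
  }
  head_idx <- 3L * (li - 1L) + 1L
  write_ndx(list(heads = head_idx), paths$ndx)
  truth <- data.frame(lipid_id = li,
                      resname = spec$resname,
                      resid = li,
                      leaflet = rep(c("upper", "lower"), each = n_per),
                      inverted = inverted)
  con <- file(paths$truth, "wb")
  writeLines(c(paste(names(truth), collapse = "\t"),
               do.call(paste, c(unname(truth), sep = "\t"))), con, sep = "\n")
  close(con)
  invisible(list(paths = paths, truth = truth, box = layout$box,
                 spec = spec, n_lipids = 2L * n_per, natoms = natoms))
}
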