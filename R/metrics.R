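#' Area per lipid from a tessellation
#'
#' The APL of a lipid is the area of the Voronoi cell generated by its key
#' atom. Inclusion generators keep their cells (they are part of the box
#' partition) but are excluded here: they are not lipids.
#'
#' @param tess A `tessellation2d`.
#' @return Data frame `lipid_id`, `apl` (nm^2).
#' @export
compute_apl <- function(tess) {
  stopifnot(inherits(tess, "tessellation2d"))
  sel <- tess$generators$kind == "lipid"
  data.frame(lipid_id = tess$generators$lipid_id[sel],
             apl = tess$areas[sel])
}

#' Per-lipid neighbor profile
#'
#' Counts the edge-sharing Voronoi neighbors of every lipid generator,
#' grouped by neighbor residue name; inclusion neighbors are counted
#' separately.
#'
#' @param tess A `tessellation2d`.
#' @return Data frame `lipid_id`, `n_neighbors` (lipid neighbors),
#'   `n_inclusion_neighbors`, and list column `neighbor_profile` (named
#'   counts by resname).
#' @export
neighbor_profile <- function(tess) {
  stopifnot(inherits(tess, "tessellation2d"))
  gen <- tess$generators
  sel <- which(gen$kind == "lipid")
  prof <- vector("list", length(sel))
  n_lip <- integer(length(sel))
  n_inc <- integer(length(sel))
  for (k in seq_along(sel)) {
    nb <- tess$adjacency[[sel[[k]]]]
    kinds <- gen$kind[nb]
    n_inc[[k]] <- sum(kinds == "inclusion")
    lipnb <- nb[kinds == "lipid"]
    n_lip[[k]] <- length(lipnb)
    tab <- table(gen$resname[lipnb])
    prof[[k]] <- setNames(as.integer(tab), names(tab))
  }
  out <- data.frame(lipid_id = gen$lipid_id[sel], n_neighbors = n_lip,
                    n_inclusion_neighbors = n_inc)
  out$neighbor_profile <- prof
  out
}

# Locate query points in a triangulation and interpolate z barycentrically.
# tri/xy/z: mesh from .leaflet_surface_mesh; qx/qy wrapped into the box.
# Barycentric coordinates are accepted down to -1e-12 (points on shared
# edges go to the lowest-indexed containing triangle); if nothing matches,
# the tolerance is relaxed to -1e-8 before giving up.
.interp_surface_z <- function(mesh, qx, qy) {
  tri <- mesh$tri
  x1 <- mesh$xy[tri[, 1], 1]; y1 <- mesh$xy[tri[, 1], 2]
  x2 <- mesh$xy[tri[, 2], 1]; y2 <- mesh$xy[tri[, 2], 2]
  x3 <- mesh$xy[tri[, 3], 1]; y3 <- mesh$xy[tri[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  z1 <- mesh$z[tri[, 1]]; z2 <- mesh$z[tri[, 2]]; z3 <- mesh$z[tri[, 3]]
  out <- numeric(length(qx))
  for (q in seq_along(qx)) {
    l1 <- ((y2 - y3) * (qx[[q]] - x3) + (x3 - x2) * (qy[[q]] - y3)) / det
    l2 <- ((y3 - y1) * (qx[[q]] - x3) + (x1 - x3) * (qy[[q]] - y3)) / det
    l3 <- 1 - l1 - l2
    hit <- which(l1 >= -1e-12 & l2 >= -1e-12 & l3 >= -1e-12)
    if (length(hit) == 0L)
      hit <- which(l1 >= -1e-8 & l2 >= -1e-8 & l3 >= -1e-8)
    if (length(hit) == 0L)
      stop2("query point (", qx[[q]], ", ", qy[[q]],
            ") outside the opposite-leaflet triangulation")
    t <- hit[[1]]
    # z1 + l2*(z2-z1) + l3*(z3-z1): exact for flat and affine surfaces
    out[[q]] <- z1[[t]] + l2[[t]] * (z2[[t]] - z1[[t]]) +
      l3[[t]] * (z3[[t]] - z1[[t]])
  }
  out
}

#' Local membrane thickness per lipid
#'
#' For each lipid, the key atom is projected onto the xy plane, the Delaunay
#' triangle of the *opposite* leaflet containing that point is found (on the
#' periodically replicated mesh, so containment is guaranteed), the opposite
#' surface height is interpolated barycentrically from the triangle's
#' vertices, and the thickness is the absolute vertical distance
#' `|z_key - z*|`. Barycentric interpolation reproduces affine surfaces
#' exactly, so flat and tilted reference bilayers give exact thicknesses.
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`.
#' @param assignment A `leaflet_assignment`.
#' @return Data frame `lipid_id`, `thickness` (nm).
#' @export
compute_thickness <- function(frame, topology, assignment) {
  stopifnot(inherits(frame, "frame_data"),
            inherits(topology, "membrane_topology"),
            inherits(assignment, "leaflet_assignment"))
  box <- frame$box[1:2]
  labs <- assignment$labels
  if (!all(c("upper", "lower") %in% labs))
    stop2("both leaflets must be populated to measure thickness")
  meshes <- list(upper = .leaflet_surface_mesh(frame, topology, assignment,
                                               "upper", box),
                 lower = .leaflet_surface_mesh(frame, topology, assignment,
                                               "lower", box))
  lp <- topology$lipids
  thick <- numeric(nrow(lp))
  for (lf in c("upper", "lower")) {
    sel <- which(labs == lf)
    if (length(sel) == 0L) next
    opp <- if (lf == "upper") "lower" else "upper"
    qx <- .wrap(frame$coords[lp$head[sel], 1], box[[1]])
    qy <- .wrap(frame$coords[lp$head[sel], 2], box[[2]])
    zstar <- .interp_surface_z(meshes[[opp]], qx, qy)
    thick[sel] <- abs(frame$coords[lp$head[sel], 3] - zstar)
  }
  data.frame(lipid_id = lp$lipid_id, thickness = thick)
}

#' Compute all per-lipid metrics for one frame
#'
#' Runs the full per-frame pipeline: per-leaflet generator construction
#' (optionally inserting inclusion atoms), periodic tessellation, APL,
#' neighbor profiles and membrane thickness.
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`.
#' @param assignment A `leaflet_assignment` (default: orientation-based).
#' @param inclusions Insert non-lipid atoms as generators (default TRUE).
#' @param slab_margin Inclusion slab margin, nm (see [insert_inclusions()]).
#' @return A `lipid_metrics` data frame (one row per lipid: `lipid_id`,
#'   `resname`, `resid`, `leaflet`, `apl`, `thickness`, `n_neighbors`,
#'   `n_inclusion_neighbors`, list column `neighbor_profile`) with
#'   attributes `frame_index`, `time`, `box` and `tessellations` (named list
#'   upper/lower, for rendering).
#' @export
compute_frame_metrics <- function(frame, topology,
                                  assignment = assign_by_orientation(frame,
                                                                     topology),
                                  inclusions = TRUE, slab_margin = 0.5) {
  box <- frame$box[1:2]
  lp <- topology$lipids
  out <- data.frame(lipid_id = lp$lipid_id, resname = lp$resname,
                    resid = lp$resid, leaflet = assignment$labels,
                    apl = NA_real_, thickness = NA_real_,
                    n_neighbors = NA_integer_,
                    n_inclusion_neighbors = NA_integer_,
                    stringsAsFactors = FALSE)
  out$neighbor_profile <- vector("list", nrow(out))
  tessellations <- list()
  for (lf in c("upper", "lower")) {
    if (!any(assignment$labels == lf)) next
    gens <- if (inclusions)
      insert_inclusions(frame, topology, assignment, lf, slab_margin)
    else lipid_generators(frame, topology, assignment, lf)
    tess <- tessellate_leaflet(gens, box)
    tessellations[[lf]] <- tess
    apl <- compute_apl(tess)
    nbr <- neighbor_profile(tess)
    row <- match(apl$lipid_id, out$lipid_id)
    out$apl[row] <- apl$apl
    out$n_neighbors[row] <- nbr$n_neighbors
    out$n_inclusion_neighbors[row] <- nbr$n_inclusion_neighbors
    out$neighbor_profile[row] <- nbr$neighbor_profile
  }
  th <- compute_thickness(frame, topology, assignment)
  out$thickness <- th$thickness[match(out$lipid_id, th$lipid_id)]
  attr(out, "frame_index") <- frame$frame_index
  attr(out, "time") <- frame$time
  attr(out, "box") <- frame$box
  attr(out, "tessellations") <- tessellations
  class(out) <- c("lipid_metrics", "data.frame")
  out
}

#' Aggregate per-lipid metrics over frames into a time series
#'
#' @param metrics_list List of `lipid_metrics` (one per frame).
#' @param statistic `"mean_apl"` or `"mean_thickness"`.
#' @param selection Lipid ids to average over (default all). Per-frame: a
#'   frame in which the selection is empty yields `NA`, not zero.
#' @param x `"frame"` (frame indices) or `"time"` (ps).
#' @param label Column name for the series (default the statistic name).
#' @return Data frame: x column plus one statistic column; attributes
#'   `xlabel`/`ylabel` carry axis annotations.
#' @export
aggregate_metrics <- function(metrics_list,
                              statistic = c("mean_apl", "mean_thickness"),
                              selection = NULL, x = c("frame", "time"),
                              label = NULL) {
  statistic <- tryCatch(match.arg(statistic),
                        error = function(e) stop2("unknown statistic '",
                                                  statistic[[1]], "'"))
  x <- match.arg(x)
  if (inherits(metrics_list, "lipid_metrics")) metrics_list <- list(metrics_list)
  field <- if (statistic == "mean_apl") "apl" else "thickness"
  xs <- vapply(metrics_list, function(mm)
    as.numeric((if (x == "frame") attr(mm, "frame_index") else attr(mm, "time")) %||% NA),
    numeric(1))
  vals <- vapply(metrics_list, function(mm) {
    v <- mm[[field]]
    if (!is.null(selection)) {
      bad <- setdiff(selection, mm$lipid_id)
      if (length(bad))
        stop2("selection contains unknown lipid id(s): ",
              paste(head(bad, 5), collapse = ", "))
      v <- v[mm$lipid_id %in% selection]
    }
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  out <- data.frame(x = xs, y = vals)
  names(out) <- c(x, label %||% statistic)
  attr(out, "xlabel") <- if (x == "frame") "frame" else "time (ps)"
  attr(out, "ylabel") <- if (statistic == "mean_apl") "APL (nm\\S2\\N)"
                         else "thickness (nm)"
  out
}
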