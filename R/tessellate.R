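# Periodic 2D tessellation of a leaflet.
#
# Periodicity is realized by ghost replication: generators wrapped into the
# primary box are copied into the eight neighboring images (within a margin),
# a Euclidean Delaunay triangulation is built over the extended set, and the
# Voronoi diagram is taken as its dual. Because every primary generator is
# then surrounded by points on all sides, its Voronoi cell is finite and
# convex by construction and no explicit clipping is needed; the cells of the
# primary generators partition the box exactly (up to round-off), which the
# constructor verifies.

.wrap <- function(v, l) v - floor(v / l) * l

#' Replicate points into periodic images
#'
#' Appends copies of the (already wrapped) points shifted by all combinations
#' of `(-lx, 0, +lx) x (-ly, 0, +ly)` that land within `margin` of the
#' primary box. With `margin >= max(lx, ly)` all eight images are kept (9n
#' points).
#'
#' @param points `n x 2` matrix of wrapped xy positions, nm.
#' @param box Length-2 `(lx, ly)`, nm.
#' @param margin Replication margin, nm (> 0).
#' @return List with `xy` (extended matrix; the first n rows are the primary
#'   points), `source` (index of the original point) and `is_image`.
#' @export
replicate_periodic <- function(points, box, margin) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  box <- as.numeric(box)
  if (length(box) != 2L || any(!is.finite(box)) || any(box <= 0))
    stop2("'box' must be two positive lengths (lx, ly)")
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0)
    stop2("'margin' must be a positive length")
  n <- nrow(points)
  xs <- list(points)
  src <- list(seq_len(n))
  for (sx in -1:1) for (sy in -1:1) {
    if (sx == 0L && sy == 0L) next
    sh <- cbind(points[, 1] + sx * box[[1]], points[, 2] + sy * box[[2]])
    keep <- sh[, 1] >= -margin & sh[, 1] <= box[[1]] + margin &
            sh[, 2] >= -margin & sh[, 2] <= box[[2]] + margin
    if (any(keep)) {
      xs[[length(xs) + 1L]] <- sh[keep, , drop = FALSE]
      src[[length(src) + 1L]] <- which(keep)
    }
  }
  xy <- do.call(rbind, xs)
  source <- unlist(src, use.names = FALSE)
  list(xy = xy, source = source,
       is_image = c(rep(FALSE, n), rep(TRUE, nrow(xy) - n)))
}

# Build a generator table for the lipids of one leaflet.
#' Lipid generators of a leaflet
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`.
#' @param assignment A `leaflet_assignment`.
#' @param leaflet `"upper"` or `"lower"`.
#' @return Generator data frame (kind `"lipid"`, key-atom positions).
#' @export
lipid_generators <- function(frame, topology, assignment,
                             leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  stopifnot(inherits(assignment, "leaflet_assignment"))
  lp <- topology$lipids[assignment$labels == leaflet, , drop = FALSE]
  data.frame(kind = rep("lipid", nrow(lp)),
             lipid_id = lp$lipid_id,
             atom_id = lp$head,
             resname = lp$resname,
             x = frame$coords[lp$head, 1],
             y = frame$coords[lp$head, 2],
             z = frame$coords[lp$head, 3],
             stringsAsFactors = FALSE)
}

#' Add non-lipid inclusion atoms to a leaflet's generators
#'
#' Atoms of residues not matching any lipid definition (protein, peptides,
#' ...) whose z position falls inside the leaflet slab
#' `[min(z_head) - slab_margin, max(z_head) + slab_margin]` are inserted as
#' extra Voronoi generators, so the surrounding lipid cells are not inflated
#' into space occupied by the inclusion.
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`.
#' @param assignment A `leaflet_assignment`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param slab_margin Slab half-extension beyond the head-atom z range, nm.
#' @return Generator data frame: lipid generators followed by inclusion
#'   generators (possibly none).
#' @export
insert_inclusions <- function(frame, topology, assignment,
                              leaflet = c("upper", "lower"),
                              slab_margin = 0.5) {
  leaflet <- match.arg(leaflet)
  gens <- lipid_generators(frame, topology, assignment, leaflet)
  non_lipid <- which(is.na(topology$atoms$lipid_id))
  if (length(non_lipid) == 0L || nrow(gens) == 0L) return(gens)
  zr <- range(gens$z)
  z <- frame$coords[non_lipid, 3]
  sel <- non_lipid[z >= zr[[1]] - slab_margin & z <= zr[[2]] + slab_margin]
  if (length(sel) == 0L) return(gens)
  inc <- data.frame(kind = rep("inclusion", length(sel)),
                    lipid_id = NA_integer_,
                    atom_id = sel,
                    resname = topology$atoms$resname[sel],
                    x = frame$coords[sel, 1],
                    y = frame$coords[sel, 2],
                    z = frame$coords[sel, 3],
                    stringsAsFactors = FALSE)
  rbind(gens, inc)
}

# deterministic per-index perturbation direction
.perturb_dir <- function(idx) {
  ang <- 2 * pi * ((idx * 7919) %% 104729) / 104729
  cbind(cos(ang), sin(ang))
}

#' Periodic Delaunay/Voronoi tessellation of one leaflet
#'
#' Builds the periodic Delaunay triangulation over the generators (lipid key
#' atoms plus any inclusion atoms) and derives the Voronoi diagram as its
#' dual. Cell areas are computed with the shoelace formula; two generators
#' are adjacent when their cells share a Voronoi edge of positive length.
#'
#' @param generators Generator data frame ([lipid_generators()] /
#'   [insert_inclusions()]), or any data frame with columns `x`, `y` (and
#'   optionally `kind`, `resname`, `lipid_id`, `atom_id`, `z`).
#' @param box Length-2 `(lx, ly)`, nm.
#' @param margin Ghost-replication margin, nm. Default: full 9-image
#'   replication (`max(lx, ly)`) for fewer than 100 generators, else
#'   `max(lx, ly) / 2`.
#' @return A `tessellation2d`: `generators` (with wrapped coordinates),
#'   `box`, `points` (replicated xy), `source`, `triangles` (index triples
#'   into `points`), `circumcenters`, `cells` (list of ccw polygon vertex
#'   matrices), `areas` (nm^2) and `adjacency` (list of neighbor generator
#'   row indices).
#' @details Exactly coincident generators are separated by a deterministic
#'   1e-9 nm perturbation (direction keyed on the generator index) with a
#'   warning. The constructor verifies that the cell areas sum to
#'   `lx * ly` within 1e-8 relative tolerance and that every cell is a
#'   polygon with at least three vertices; on failure it retries once with a
#'   1e-11 nm global perturbation before giving up.
#' @export
tessellate_leaflet <- function(generators, box, margin = NULL) {
  if (is.matrix(generators))
    generators <- data.frame(x = generators[, 1], y = generators[, 2])
  if (!all(c("x", "y") %in% names(generators)))
    stop2("'generators' needs columns x and y")
  box <- as.numeric(box)
  if (length(box) != 2L || any(!is.finite(box)) || any(box <= 0))
    stop2("'box' must be two positive lengths (lx, ly)")
  G <- nrow(generators)
  if (G < 3L) stop2("need at least 3 generators, got ", G)
  if (is.null(generators$kind)) generators$kind <- "lipid"

  gx <- .wrap(generators$x, box[[1]])
  gy <- .wrap(generators$y, box[[2]])

  dup <- duplicated(cbind(gx, gy))
  if (any(dup)) {
    warning(sum(dup), " coincident generator position(s) perturbed by 1e-9 nm",
            call. = FALSE)
    d <- .perturb_dir(which(dup))
    gx[dup] <- .wrap(gx[dup] + 1e-9 * d[, 1], box[[1]])
    gy[dup] <- .wrap(gy[dup] + 1e-9 * d[, 2], box[[2]])
  }
  if (is.null(margin))
    margin <- if (G < 100L) max(box) else max(box) / 2

  build <- function(gx, gy) {
    rep_pts <- replicate_periodic(cbind(gx, gy), box, margin)
    del <- .Call(C_delaunay, rep_pts$xy[, 1], rep_pts$xy[, 2])
    tri <- del$triangles
    cc <- del$circumcenters
    # incidence of replicated points in triangles
    m <- nrow(tri)
    tri_of <- rep.int(seq_len(m), 3L)
    verts <- as.vector(tri)
    inc <- split(tri_of, factor(verts, levels = seq_len(nrow(rep_pts$xy))))

    cells <- vector("list", G)
    areas <- numeric(G)
    for (i in seq_len(G)) {
      ti <- inc[[i]]
      if (length(ti) < 3L) return(NULL)
      px <- cc[ti, 1]
      py <- cc[ti, 2]
      o <- order(atan2(py - gy[[i]], px - gx[[i]]))
      px <- px[o]; py <- py[o]
      # shoelace (duplicated vertices from co-circular triangles are harmless)
      j <- c(seq_along(px)[-1], 1L)
      areas[[i]] <- 0.5 * sum(px * py[j] - px[j] * py)
      keep <- sqrt((px - px[c(length(px), seq_len(length(px) - 1L))])^2 +
                   (py - py[c(length(py), seq_len(length(py) - 1L))])^2) > 1e-9
      if (sum(keep) < 3L) return(NULL)
      cells[[i]] <- cbind(x = px[keep], y = py[keep])
    }
    if (any(areas <= 0)) return(NULL)
    if (abs(sum(areas) - box[[1]] * box[[2]]) >
        1e-8 * box[[1]] * box[[2]]) return(NULL)

    # adjacency via dual edges of positive length
    e1 <- pmin(tri[, c(1, 2, 3)], tri[, c(2, 3, 1)])
    e2 <- pmax(tri[, c(1, 2, 3)], tri[, c(2, 3, 1)])
    ekey <- paste(e1, e2)
    et <- rep.int(seq_len(m), 3L)
    first <- match(ekey, ekey)
    is_second <- first != seq_along(ekey)
    # pair up the two triangles of each interior edge
    t1 <- et[first[is_second]]
    t2 <- et[is_second]
    pa <- as.vector(e1)[first[is_second]]
    pb <- as.vector(e2)[first[is_second]]
    dual_len <- sqrt((cc[t1, 1] - cc[t2, 1])^2 + (cc[t1, 2] - cc[t2, 2])^2)
    keep <- dual_len > 1e-7 & (pa <= G | pb <= G)
    pa <- pa[keep]; pb <- pb[keep]
    t1 <- t1[keep]; t2 <- t2[keep]
    sa <- rep_pts$source[pa]
    sb <- rep_pts$source[pb]
    selA <- pa <= G
    selB <- pb <= G
    from <- c(pa[selA], pb[selB])
    to <- c(sb[selA], sa[selB])
    adjacency <- vector("list", G)
    sp <- split(to, from)
    for (nm in names(sp)) adjacency[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
    # (in very small periodic systems distinct neighbor slots can collapse
    # onto the same source generator, so no minimum degree is enforced here)
    # dual (Voronoi) edge endpoints per adjacency, for diagnostics/oracles
    edge_tab <- data.frame(a = from, b = to,
                           x1 = c(cc[t1[selA], 1], cc[t1[selB], 1]),
                           y1 = c(cc[t1[selA], 2], cc[t1[selB], 2]),
                           x2 = c(cc[t2[selA], 1], cc[t2[selB], 1]),
                           y2 = c(cc[t2[selA], 2], cc[t2[selB], 2]))
    list(rep_pts = rep_pts, tri = tri, cc = cc, cells = cells, areas = areas,
         adjacency = adjacency, edges = edge_tab,
         degenerate = del$degenerate)
  }

  res <- build(gx, gy)
  if (is.null(res)) {
    warning("degenerate tessellation; retrying with 1e-11 nm perturbation",
            call. = FALSE)
    d <- .perturb_dir(seq_len(G))
    res <- build(.wrap(gx + 1e-11 * d[, 1], box[[1]]),
                 .wrap(gy + 1e-11 * d[, 2], box[[2]]))
  }
  if (is.null(res))
    stop2("tessellation failed validation (degenerate generator geometry)")

  generators$x <- gx
  generators$y <- gy
  structure(list(generators = generators, box = box,
                 points = res$rep_pts$xy, source = res$rep_pts$source,
                 triangles = res$tri, circumcenters = res$cc,
                 cells = res$cells, areas = res$areas,
                 adjacency = res$adjacency, edges = res$edges),
            class = "tessellation2d")
}

#' @export
print.tessellation2d <- function(x, ...) {
  cat(sprintf(
    "<tessellation2d> %d generators (%d lipid, %d inclusion) in %.3g x %.3g nm box\n",
    nrow(x$generators), sum(x$generators$kind == "lipid"),
    sum(x$generators$kind == "inclusion"), x$box[1], x$box[2]))
  cat(sprintf("  %d triangles, cell areas %.4g..%.4g nm^2 (sum %.6g)\n",
              nrow(x$triangles), min(x$areas), max(x$areas), sum(x$areas)))
  invisible(x)
}

# Delaunay triangulation of one leaflet's key atoms over replicated points;
# used for thickness interpolation. Returns triangles, replicated points and
# their z values.
.leaflet_surface_mesh <- function(frame, topology, assignment, leaflet, box) {
  lp <- topology$lipids[assignment$labels == leaflet, , drop = FALSE]
  if (nrow(lp) < 3L)
    stop2("leaflet '", leaflet, "' has ", nrow(lp),
          " lipids; need at least 3 to triangulate")
  x <- .wrap(frame$coords[lp$head, 1], box[[1]])
  y <- .wrap(frame$coords[lp$head, 2], box[[2]])
  z <- frame$coords[lp$head, 3]
  margin <- if (nrow(lp) < 100L) max(box) else max(box) / 2
  rep_pts <- replicate_periodic(cbind(x, y), box, margin)
  del <- .Call(C_delaunay, rep_pts$xy[, 1], rep_pts$xy[, 2])
  list(tri = del$triangles, xy = rep_pts$xy,
       z = z[rep_pts$source], source = rep_pts$source)
}
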