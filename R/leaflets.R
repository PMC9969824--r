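#' Fit a polynomial midsurface z = f(x, y)
#'
#' Ordinary least squares on the monomial basis `x^a y^b` with `a + b <= d`
#' (`(d+1)(d+2)/2` coefficients). With lipid head atoms as input this is the
#' bilayer midsurface used by position-based leaflet detection; the fit costs
#' O(n d^2) per evaluation of the normal equations' design.
#'
#' @param points `n x 3` matrix of (x, y, z) in nm.
#' @param degree Polynomial degree d >= 0.
#' @return A `poly_surface` with `degree`, `powers` (two-column matrix of
#'   exponents) and `coeffs`.
#' @export
fit_midplane <- function(points, degree = 2L) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop2("'points' must be an n x 3 matrix")
  if (!is_count(degree) || degree < 0) stop2("'degree' must be an integer >= 0")
  degree <- as.integer(degree)
  powers <- .monomial_powers(degree)
  m <- nrow(powers)
  n <- nrow(points)
  if (n < m)
    stop2("underdetermined fit: degree ", degree, " needs at least ", m,
          " points, got ", n)
  X <- .design_matrix(points[, 1], points[, 2], powers)
  qr_x <- qr(X)
  if (qr_x$rank < m)
    stop2("rank-deficient design (points degenerate in xy, e.g. collinear); ",
          "cannot fit degree ", degree)
  coeffs <- qr.coef(qr_x, points[, 3])
  structure(list(degree = degree, powers = powers,
                 coeffs = as.numeric(coeffs)),
            class = "poly_surface")
}

.monomial_powers <- function(degree) {
  pw <- expand.grid(a = 0:degree, b = 0:degree)
  pw <- pw[pw$a + pw$b <= degree, , drop = FALSE]
  pw <- pw[order(pw$a + pw$b, pw$a), , drop = FALSE]
  as.matrix(pw)
}

.design_matrix <- function(x, y, powers) {
  X <- matrix(1, length(x), nrow(powers))
  for (j in seq_len(nrow(powers)))
    X[, j] <- x^powers[j, 1] * y^powers[j, 2]
  X
}

#' Evaluate a fitted surface
#' @param surface A `poly_surface`.
#' @param x,y Coordinates, nm.
#' @return Surface heights z = f(x, y), nm.
#' @export
eval_surface <- function(surface, x, y) {
  stopifnot(inherits(surface, "poly_surface"))
  drop(.design_matrix(x, y, surface$powers) %*% surface$coeffs)
}

#' @export
print.poly_surface <- function(x, ...) {
  terms <- sprintf("%.4g x^%d y^%d", x$coeffs, x$powers[, 1], x$powers[, 2])
  cat("<poly_surface> degree", x$degree, ": z =",
      paste(terms, collapse = " + "), "\n")
  invisible(x)
}

.new_assignment <- function(labels, method, degree = NULL, surface = NULL) {
  structure(list(labels = labels, method = method, degree = degree,
                 surface = surface),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat(sprintf("<leaflet_assignment> %s method: %d upper, %d lower\n",
              x$method, sum(x$labels == "upper"), sum(x$labels == "lower")))
  invisible(x)
}

#' Orientation-based leaflet assignment
#'
#' The classic rule: a lipid's orientation vector points from the mean of its
#' tail terminal atoms to its head atom; a positive z component means the
#' head sits above the tails, i.e. the upper leaflet. Fails for lipids whose
#' conformation inverts the head-tail order (see [assign_by_position()]).
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`; every lipid needs at least one
#'   resolved tail atom.
#' @return A `leaflet_assignment` with per-lipid labels `"upper"`/`"lower"`.
#' @export
assign_by_orientation <- function(frame, topology) {
  stopifnot(inherits(frame, "frame_data"),
            inherits(topology, "membrane_topology"))
  lp <- topology$lipids
  no_tail <- lengths(lp$tails) == 0L
  if (any(no_tail))
    stop2("orientation-based detection needs tail atoms; none resolved for ",
          "residue(s) ", paste(unique(sprintf("%s %d", lp$resname[no_tail],
                                              lp$resid[no_tail])),
                               collapse = ", "))
  zhead <- frame$coords[lp$head, 3]
  ztail <- vapply(lp$tails, function(ix) mean(frame$coords[ix, 3]), numeric(1))
  dz <- zhead - ztail
  if (any(dz == 0))
    warning(sum(dz == 0), " lipid(s) with exactly horizontal orientation ",
            "assigned to the upper leaflet", call. = FALSE)
  .new_assignment(ifelse(dz >= 0, "upper", "lower"), "orientation")
}

#' Position-based leaflet assignment
#'
#' Fits a polynomial midsurface through all lipid key atoms
#' ([fit_midplane()]) and labels each lipid by the sign of its key atom's
#' vertical residual. Robust where orientation fails (inverted conformers,
#' lipids distorted around proteins). Lipids exactly on the surface fall back
#' to the orientation rule, with a warning.
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`.
#' @param degree Midsurface polynomial degree (default 2).
#' @param all_atoms Fit to all lipid atoms instead of key atoms only.
#' @return A `leaflet_assignment` carrying the fitted surface.
#' @export
assign_by_position <- function(frame, topology, degree = 2L,
                               all_atoms = FALSE) {
  stopifnot(inherits(frame, "frame_data"),
            inherits(topology, "membrane_topology"))
  lp <- topology$lipids
  fit_idx <- if (all_atoms) {
    unlist(c(lp$head, lp$tails), use.names = FALSE)
  } else lp$head
  surface <- fit_midplane(frame$coords[fit_idx, , drop = FALSE], degree)
  res <- frame$coords[lp$head, 3] -
    eval_surface(surface, frame$coords[lp$head, 1], frame$coords[lp$head, 2])
  labels <- ifelse(res > 0, "upper", "lower")
  on_surface <- res == 0
  if (any(on_surface)) {
    warning(sum(on_surface), " lipid(s) exactly on the midsurface; falling ",
            "back to the orientation rule for them", call. = FALSE)
    fallback <- assign_by_orientation(frame, topology)
    labels[on_surface] <- fallback$labels[on_surface]
  }
  .new_assignment(labels, "position", degree = as.integer(degree),
                  surface = surface)
}

#' Assign lipids to leaflets
#'
#' Front end dispatching to [assign_by_orientation()] or
#' [assign_by_position()].
#'
#' @param frame A `frame_data`.
#' @param topology A `membrane_topology`.
#' @param method `"orientation"` or `"position"`.
#' @param degree Midsurface degree (position method only).
#' @param all_atoms Fit the midsurface to all lipid atoms (position method).
#' @return A `leaflet_assignment`.
#' @export
assign_leaflets <- function(frame, topology,
                            method = c("orientation", "position"),
                            degree = 2L, all_atoms = FALSE) {
  method <- match.arg(method)
  if (method == "orientation") assign_by_orientation(frame, topology)
  else assign_by_position(frame, topology, degree, all_atoms)
}
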