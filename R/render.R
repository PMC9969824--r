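#' Render a leaflet's Voronoi diagram to a PNG image
#'
#' Every pixel is assigned to its nearest generator under the minimum-image
#' metric (which *is* the periodic Voronoi diagram, so the raster is exact at
#' pixel resolution), filled with the color of that generator's metric value,
#' and cell borders are drawn where ownership changes. The legend (color bar
#' with vmin/vmax labels) sits in the top-left corner, the leaflet label in
#' the top-right. Inclusion cells use a reserved neutral grey; highlighted
#' (selected) cells are overlaid with the selection blue. Rendering is fully
#' deterministic: identical inputs give byte-identical files.
#'
#' @param tess A `tessellation2d`.
#' @param values Metric value per lipid generator, either a vector along the
#'   lipid generators or named/matched by `lipid_id`.
#' @param scale A [color_scale()]; default linear grey over the value range.
#' @param highlight Lipid ids to overlay with the selection color.
#' @param out_path Output PNG path.
#' @param width Image width in pixels (height follows the box aspect ratio).
#' @param label Text drawn top-right (e.g. `"UPPER LEAFLET"`).
#' @return `out_path`, invisibly.
#' @export
render_voronoi_map <- function(tess, values, scale = NULL,
                               highlight = integer(), out_path,
                               width = 512L, label = "") {
  stopifnot(inherits(tess, "tessellation2d"))
  gen <- tess$generators
  is_lip <- gen$kind == "lipid"
  nlip <- sum(is_lip)
  if (length(values) != nlip)
    stop2("'values' must have one value per lipid generator (", nlip, ")")
  if (is.null(scale)) {
    rng <- range(values, finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[[1]] >= rng[[2]]) rng <- rng + c(-0.5, 0.5)
    scale <- color_scale("linear_grey", rng[[1]], rng[[2]])
  }
  box <- tess$box
  width <- as.integer(width)
  height <- max(8L, as.integer(round(width * box[[2]] / box[[1]])))

  # per-generator fill colors (0..1)
  fill <- matrix(0.6, nrow(gen), 3)  # neutral inclusion grey
  fill[is_lip, ] <- map_color(values, scale) / 255
  sel_col <- c(0.25, 0.45, 0.95)
  hi <- is_lip & gen$lipid_id %in% highlight
  if (any(hi)) fill[hi, ] <- matrix(sel_col, sum(hi), 3, byrow = TRUE)

  # ownership raster: nearest generator under the minimum-image metric
  pxx <- (seq_len(width) - 0.5) / width * box[[1]]
  pxy <- (height - seq_len(height) + 0.5) / height * box[[2]]  # row 1 = top
  owner <- matrix(0L, height, width)
  gx <- gen$x; gy <- gen$y
  for (r in seq_len(height)) {
    dy <- abs(pxy[[r]] - gy)
    dy <- pmin(dy, box[[2]] - dy)
    best <- rep.int(1L, width)
    bestd <- rep.int(Inf, width)
    for (g in seq_along(gx)) {
      dx <- abs(pxx - gx[[g]])
      dx <- pmin(dx, box[[1]] - dx)
      d2 <- dx * dx + dy[[g]] * dy[[g]]
      upd <- d2 < bestd
      best[upd] <- g
      bestd[upd] <- d2[upd]
    }
    owner[r, ] <- best
  }

  cv <- .new_canvas(width, height)
  for (ch in 1:3)
    cv[, , ch] <- matrix(fill[owner, ch], height, width)
  # borders where ownership changes (right/down neighbor differs)
  eh <- owner[, -width] != owner[, -1]
  ev <- owner[-height, ] != owner[-1, ]
  bmask <- matrix(FALSE, height, width)
  bmask[, -width] <- bmask[, -width] | eh
  bmask[-height, ] <- bmask[-height, ] | ev
  for (ch in 1:3) {
    plane <- cv[, , ch]
    plane[bmask] <- 0
    cv[, , ch] <- plane
  }

  # legend: fixed-size color bar, top-left
  if (scale$name != "none") {
    bar_h <- max(24L, height %/% 4L)
    bar_w <- 14L
    m0 <- 8L
    cv <- .cv_rect(cv, m0 - 2L, m0 - 2L, m0 + bar_h + 1L, m0 + bar_w + 1L,
                   c(1, 1, 1))
    tt <- scale$vmax - (seq_len(bar_h) - 0.5) / bar_h *
      (scale$vmax - scale$vmin)
    cols <- map_color(tt, scale) / 255
    for (r in seq_len(bar_h))
      cv <- .cv_rect(cv, m0 + r - 1L, m0, m0 + r - 1L, m0 + bar_w - 1L,
                     cols[r, ])
    cv <- .cv_text(cv, m0, m0 + bar_w + 4L, formatC(scale$vmax, format = "g"))
    cv <- .cv_text(cv, m0 + bar_h - 7L, m0 + bar_w + 4L,
                   formatC(scale$vmin, format = "g"))
  }
  # leaflet label, top-right
  if (nzchar(label)) {
    tw <- 6L * nchar(label)
    cv <- .cv_rect(cv, 6L, width - tw - 10L, 16L, width - 2L, c(1, 1, 1))
    cv <- .cv_text(cv, 8L, width - tw - 6L, label)
  }
  .cv_write_png(cv, out_path)
  invisible(out_path)
}

#' Plot a time series to a PNG image
#'
#' Line plot with one line per column, axis ticks and labels, and a legend.
#' Drawn on the package's deterministic raster canvas, so identical input
#' yields byte-identical files.
#'
#' @param series Data frame: first column x, remaining columns series.
#'   Attributes `xlabel`/`ylabel` are used for axis labels when present.
#' @param out_path Output PNG path.
#' @param width,height Image size in pixels.
#' @return `out_path`, invisibly.
#' @export
plot_series <- function(series, out_path, width = 720L, height = 480L) {
  series <- as.data.frame(series)
  if (nrow(series) == 0L || ncol(series) < 2L)
    stop2("'series' must have at least one row and one data column")
  x <- as.numeric(series[[1]])
  ys <- series[-1]
  palette <- list(c(0.12, 0.30, 0.80), c(0.85, 0.20, 0.15),
                  c(0.10, 0.55, 0.25), c(0.90, 0.55, 0.10),
                  c(0.55, 0.15, 0.65), c(0.10, 0.60, 0.60))

  ml <- 64L; mr <- 16L; mt <- 20L; mb <- 44L
  pw <- width - ml - mr
  ph <- height - mt - mb
  xr <- range(x, finite = TRUE)
  yr <- range(unlist(ys), finite = TRUE)
  if (!all(is.finite(yr))) stop2("series has no finite values")
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  yr <- yr + c(-0.05, 0.05) * diff(yr)

  to_col <- function(v) ml + 1L + round((v - xr[[1]]) / diff(xr) * (pw - 1L))
  to_row <- function(v) mt + ph - round((v - yr[[1]]) / diff(yr) * (ph - 1L))

  cv <- .new_canvas(width, height)
  cv <- .cv_rect(cv, mt, ml, mt + ph, ml + 1L, c(0, 0, 0))       # y axis
  cv <- .cv_rect(cv, mt + ph, ml, mt + ph + 1L, ml + pw, c(0, 0, 0))  # x axis
  for (tk in pretty(xr, 5)) {
    if (tk < xr[[1]] || tk > xr[[2]]) next
    cc <- to_col(tk)
    cv <- .cv_rect(cv, mt + ph + 2L, cc, mt + ph + 5L, cc, c(0, 0, 0))
    lab <- formatC(tk, format = "g")
    cv <- .cv_text(cv, mt + ph + 8L, cc - 3L * nchar(lab), lab)
  }
  for (tk in pretty(yr, 5)) {
    if (tk < yr[[1]] || tk > yr[[2]]) next
    rr <- to_row(tk)
    cv <- .cv_rect(cv, rr, ml - 4L, rr, ml, c(0, 0, 0))
    lab <- formatC(tk, format = "g")
    cv <- .cv_text(cv, rr - 3L, ml - 6L - 6L * nchar(lab), lab)
  }
  xlab <- attr(series, "xlabel") %||% names(series)[[1]]
  ylab <- attr(series, "ylabel") %||% "value"
  cv <- .cv_text(cv, height - 10L, ml + (pw - 6L * nchar(xlab)) %/% 2L, xlab)
  cv <- .cv_text(cv, 4L, 4L, ylab)

  for (k in seq_along(ys)) {
    col <- palette[[(k - 1L) %% length(palette) + 1L]]
    yv <- as.numeric(ys[[k]])
    ok <- is.finite(yv) & is.finite(x)
    idx <- which(ok)
    if (length(idx) >= 2L) {
      for (j in seq_len(length(idx) - 1L)) {
        a <- idx[[j]]; b <- idx[[j + 1L]]
        if (b - a > 1L) next  # gap across missing values
        cv <- .cv_line(cv, to_row(yv[[a]]), to_col(x[[a]]),
                       to_row(yv[[b]]), to_col(x[[b]]), col)
      }
    } else if (length(idx) == 1L) {
      cv <- .cv_rect(cv, to_row(yv[[idx]]) - 1L, to_col(x[[idx]]) - 1L,
                     to_row(yv[[idx]]) + 1L, to_col(x[[idx]]) + 1L, col)
    }
    # legend entry
    lr <- mt + 4L + 10L * (k - 1L)
    lc <- ml + pw - 6L * nchar(names(ys)[[k]]) - 26L
    cv <- .cv_rect(cv, lr + 3L, lc, lr + 3L, lc + 14L, col)
    cv <- .cv_text(cv, lr, lc + 18L, names(ys)[[k]])
  }
  .cv_write_png(cv, out_path)
  invisible(out_path)
}
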