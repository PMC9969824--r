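# Color scales for the Voronoi views.
#
# Stop tables are pinned so renders are reproducible:
#   rainbow      blue - cyan - green - yellow - red
#   locs         a 256-entry luminance-monotone table shipped in
#                inst/extdata/locs_scale_synthetic.csv. The original
#                "linear optimized color scale" is published only as a
#                reference to external work, so this table is a synthetic
#                stand-in with the same design goals (luminance rises
#                linearly black -> white through blue/magenta/orange/yellow).
#   heated_object black - red - yellow - white
#   linear_grey  black - white
#   none         constant white fill (cells distinguished by borders only)

.locs_stops <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "locs_scale_synthetic.csv",
                          package = "lipidvoro", mustWork = TRUE)
      tab <- read.table(path, header = TRUE, sep = ",")
      cache <<- cbind(t = tab$t, r = tab$r, g = tab$g, b = tab$b)
    }
    cache
  }
})

.scale_stops <- function(name) {
  switch(name,
    rainbow = cbind(t = c(0, 0.25, 0.5, 0.75, 1),
                    r = c(0, 0, 0, 255, 255),
                    g = c(0, 255, 255, 255, 0),
                    b = c(255, 255, 0, 0, 0)),
    heated_object = cbind(t = c(0, 0.4, 0.8, 1),
                          r = c(0, 255, 255, 255),
                          g = c(0, 0, 255, 255),
                          b = c(0, 0, 0, 255)),
    linear_grey = cbind(t = c(0, 1), r = c(0, 255), g = c(0, 255),
                        b = c(0, 255)),
    locs = .locs_stops(),
    none = cbind(t = c(0, 1), r = c(255, 255), g = c(255, 255),
                 b = c(255, 255)),
    stop2("unknown color scale '", name, "'"))
}

#' Construct a color scale
#'
#' @param name One of `"rainbow"`, `"locs"`, `"heated_object"`,
#'   `"linear_grey"`, `"none"`.
#' @param vmin,vmax Metric values mapped to the scale ends; values outside
#'   are clamped. `vmin < vmax` required.
#' @return A `color_scale`.
#' @export
color_scale <- function(name = c("rainbow", "locs", "heated_object",
                                 "linear_grey", "none"),
                        vmin = 0, vmax = 1) {
  name <- match.arg(name)
  if (!is.finite(vmin) || !is.finite(vmax) || vmin >= vmax)
    stop2("'vmin' must be smaller than 'vmax'")
  structure(list(name = name, vmin = vmin, vmax = vmax,
                 stops = .scale_stops(name)),
            class = "color_scale")
}

#' @export
print.color_scale <- function(x, ...) {
  cat(sprintf("<color_scale> %s over [%g, %g] (%d stops)\n", x$name, x$vmin,
              x$vmax, nrow(x$stops)))
  invisible(x)
}

#' Map metric values to RGB colors
#'
#' Values are normalized to `t = (value - vmin) / (vmax - vmin)`, clamped to
#' `[0, 1]`, then piecewise-linearly interpolated between the scale's stops.
#' Channels are rounded half-up to integers 0..255.
#'
#' @param values Numeric vector.
#' @param scale A [color_scale()].
#' @return Integer matrix `n x 3` (columns r, g, b).
#' @export
map_color <- function(values, scale) {
  stopifnot(inherits(scale, "color_scale"))
  t <- (values - scale$vmin) / (scale$vmax - scale$vmin)
  t <- pmin(pmax(t, 0), 1)
  st <- scale$stops
  out <- vapply(c("r", "g", "b"), function(ch)
    floor(approx(st[, "t"], st[, ch], xout = t, rule = 2)$y + 0.5),
    numeric(length(t)))
  if (length(t) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(NULL, c("r", "g", "b")))
  storage.mode(out) <- "integer"
  out
}
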