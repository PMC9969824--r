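test_that("map_color hits endpoints, clamps, and rounds half-up", {
  grey <- color_scale("linear_grey", 0, 1)
  expect_equal(map_color(0, grey)[1, ], c(r = 0L, g = 0L, b = 0L))
  expect_equal(map_color(1, grey)[1, ], c(r = 255L, g = 255L, b = 255L))
  expect_equal(map_color(0.5, grey)[1, ], c(r = 128L, g = 128L, b = 128L))
  # clamping: out-of-range values take the endpoint color
  for (nm in c("rainbow", "locs", "heated_object", "linear_grey")) {
    sc <- color_scale(nm, 0.2, 1.6)
    expect_equal(map_color(-5, sc), map_color(0.2, sc))
    expect_equal(map_color(99, sc), map_color(1.6, sc))
  }
  expect_error(color_scale("linear_grey", 1, 1), "vmin")
  expect_error(color_scale("sunset", 0, 1), "arg")
})

test_that("color scales are monotone along their stop ordering", {
  vals <- seq(0, 1, length.out = 101)
  for (nm in c("locs", "linear_grey", "heated_object")) {
    sc <- color_scale(nm, 0, 1)
    rgb <- map_color(vals, sc)
    # luminance-ordered scales: Rec.601 luminance must not decrease
    lum <- rgb %*% c(0.299, 0.587, 0.114)
    expect_true(all(diff(lum) >= -1e-6), info = nm)
  }
  # rainbow is monotone channel-by-channel between consecutive stops
  sc <- color_scale("rainbow", 0, 1)
  rgb <- map_color(vals, sc)
  expect_equal(rgb[1, ], c(r = 0L, g = 0L, b = 255L))      # blue end
  expect_equal(rgb[101, ], c(r = 255L, g = 0L, b = 0L))    # red end
})

test_that("voronoi maps fill cells, highlight selections, deterministically", {
  g <- expand.grid(x = c(1, 3), y = c(1, 3))
  gens <- data.frame(kind = "lipid", lipid_id = 1:4, atom_id = 1:4,
                     resname = "DPPC", x = g$x, y = g$y, z = 0)
  tess <- tessellate_leaflet(gens, c(4, 4))
  sc <- color_scale("rainbow", 0, 1)
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  p3 <- tempfile(fileext = ".png")

  render_voronoi_map(tess, rep(0.5, 4), sc, out_path = p1, width = 128)
  img <- png::readPNG(p1)
  # constant metric: sampled points inside all four cells (clear of the
  # legend area) share one fill color
  centers <- rbind(c(96, 32), c(96, 96), c(32, 96), c(56, 56))  # row, col
  cols <- apply(centers, 1, function(rc) img[rc[[1]], rc[[2]], ])
  expect_equal(cols[, 2], cols[, 1])
  expect_equal(cols[, 3], cols[, 1])
  expect_equal(cols[, 4], cols[, 1])

  # highlighting changes the highlighted cell's pixels only
  render_voronoi_map(tess, rep(0.5, 4), sc, highlight = 1L, out_path = p2,
                     width = 128)
  img2 <- png::readPNG(p2)
  expect_false(isTRUE(all.equal(img2[96, 32, ], img[96, 32, ])))
  expect_equal(img2[96, 96, ], img[96, 96, ])

  # byte-identical reruns
  render_voronoi_map(tess, rep(0.5, 4), sc, out_path = p3, width = 128)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p3, "raw", file.size(p3)))

  expect_error(render_voronoi_map(tess, 1:3, sc, out_path = p1), "per lipid")
})

test_that("series plots are deterministic with one legend entry per column", {
  df <- data.frame(frame = 0:20,
                   simA = 0.6 + 0.01 * sin(0:20),
                   simB = 0.62 + 0.01 * cos(0:20))
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  plot_series(df, p1, width = 320, height = 200)
  plot_series(df, p2, width = 320, height = 200)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # constant series draw a horizontal line: the line color occupies exactly
  # one pixel row in the plot interior
  dfc <- data.frame(frame = 0:10, flat = rep(1, 11))
  plot_series(dfc, p1, width = 320, height = 200)
  img <- png::readPNG(p1)
  line_px <- which(abs(img[, , 1] - 0.12) < 0.01 &
                     abs(img[, , 3] - 0.80) < 0.01, arr.ind = TRUE)
  interior <- line_px[line_px[, 2] > 70 & line_px[, 2] < 250, , drop = FALSE]
  expect_gt(nrow(interior), 50)
  expect_equal(min(interior[, 1]), max(interior[, 1]))

  expect_error(plot_series(data.frame(x = numeric()), p1), "at least")
})
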