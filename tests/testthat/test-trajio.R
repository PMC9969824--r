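test_that("frame_range arithmetic matches the closed form", {
  set.seed(42)
  for (rep in 1:50) {
    first <- sample(0:20, 1)
    last <- first + sample(0:50, 1)
    stride <- sample(1:7, 1)
    rng <- frame_range(first, last, stride)
    idx <- lipidvoro:::.range_indices(rng, n_frames = last + 10L)
    expect_equal(length(idx), floor((last - first) / stride) + 1)
    expect_equal(idx[[1]], first)
    expect_true(all(idx <= last))
  }
  expect_error(frame_range(5, 4), "last")
  expect_error(frame_range(0, 10, 0), "stride")
})

test_that("read_topology resolves lipids and reports problems", {
  res <- make_bilayer(nx = 2, ny = 2, spacing = 1, thickness = 4, seed = 3)
  expect_equal(n_lipids(res$topology), 8)
  expect_equal(res$topology$natoms, 24)
  expect_equal(res$topology$lipids$resname, rep("DPPC", 8))
  # reference coordinates come back in nm
  ref <- reference_frame(res$topology)
  expect_equal(ref$box, res$box, tolerance = 1e-6)

  # no residue matches any definition -> 0 lipids with a warning
  expect_warning(
    topo0 <- read_topology(res$paths$pdb, list(lipid_def("POPC"))),
    "0 lipids")
  expect_equal(n_lipids(topo0), 0)

  # matching residue without the head atom -> error naming the residue
  expect_error(
    read_topology(res$paths$pdb, list(lipid_def("DPPC", head_atom = "P8"))),
    "DPPC 1")
})

test_that("trajectory range selection yields the requested frames", {
  res <- make_bilayer(nx = 2, ny = 2, spacing = 1, thickness = 4,
                      n_frames = 12, seed = 5, jitter_z = 0.01)
  topo <- res$topology
  frames <- read_trajectory(res$paths$traj, topo, frame_range(0, 11, 3))
  expect_length(frames, 4)
  expect_equal(vapply(frames, `[[`, integer(1), "frame_index"), c(0L, 3L, 6L, 9L))
  one <- read_trajectory(res$paths$traj, topo, frame_range(10, 10))
  expect_length(one, 1)
  expect_equal(one[[1]]$frame_index, 10L)
  # open-ended range reads to the end
  expect_length(read_trajectory(res$paths$traj, topo, frame_range(5)), 7)
})

test_that("atom count mismatches are refused", {
  a <- make_bilayer(nx = 2, ny = 2, spacing = 1, thickness = 4, seed = 1)
  b <- make_bilayer(nx = 3, ny = 2, spacing = 1, thickness = 4, seed = 1)
  expect_error(open_trajectory(a$paths$traj, b$topology), "mismatch")
})

test_that("XTC round trip is within the precision quantum", {
  set.seed(11)
  coords <- matrix(runif(3 * 200, 0, 9), ncol = 3)
  box <- c(9, 7, 12)
  path <- tempfile(fileext = ".xtc")
  write_xtc_frame(path, coords, box, step = 3L, time = 1.5,
                  precision = 1000)
  scan <- .Call(lipidvoro:::C_xtc_scan, path)
  fr <- .Call(lipidvoro:::C_xtc_read_frame, path, scan$offset[[1]])
  expect_lte(max(abs(fr$coords - coords)), 0.001)
  expect_equal(fr$time, 1.5, tolerance = 1e-7)
  expect_equal(fr$step, 3L)
})

test_that("XTC codec agrees with an independent reader (MDAnalysis)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(12)
  coords <- matrix(runif(3 * 64, 0, 6), ncol = 3)
  path <- tempfile(fileext = ".xtc")
  out <- tempfile(fileext = ".txt")
  write_xtc_frame(path, coords, c(6, 6, 10), step = 0L, time = 0)
  status <- system2("python", c("-c", shQuote(sprintf(
    "import MDAnalysis as mda, numpy; r = mda.coordinates.XTC.XTCReader('%s'); numpy.savetxt('%s', r[0].positions / 10.0)",
    path, out))))
  skip_if(status != 0, "MDAnalysis unavailable")
  got <- as.matrix(read.table(out))
  # the two readers must decode the same stored (quantized) values
  scan <- .Call(lipidvoro:::C_xtc_scan, path)
  mine <- .Call(lipidvoro:::C_xtc_read_frame, path, scan$offset[[1]])$coords
  expect_lt(max(abs(got - mine)), 1e-5)
  expect_lte(max(abs(mine - coords)), 0.001)
})

test_that("TRR double-precision round trip is bit-faithful", {
  set.seed(13)
  coords <- matrix(runif(3 * 50, 0, 8), ncol = 3)
  path <- tempfile(fileext = ".trr")
  write_trr_frame(path, coords, c(8, 8, 11), step = 7L, time = 2.25)
  write_trr_frame(path, coords * 0.3, c(8, 8, 11), step = 8L, time = 2.5,
                  append = TRUE)
  scan <- lipidvoro:::.trr_scan(path)
  expect_equal(scan$natoms, 50L)
  expect_length(scan$offset, 2)
  f1 <- lipidvoro:::.trr_read_frame(scan, 1)
  f2 <- lipidvoro:::.trr_read_frame(scan, 2)
  expect_identical(f1$coords, coords)       # bit-faithful
  expect_identical(f2$coords, coords * 0.3)
  expect_equal(f1$time, 2.25)
  expect_equal(diag(f2$box), c(8, 8, 11))
})

test_that("NDX read/write is a bijection with deterministic tie-breaks", {
  path <- tempfile(fileext = ".ndx")
  writeLines(c("[ heads ]", "1 2 3", "[ sel ]", "4 5", "[ sel ]", "9",
               "[ empty ]"), path)
  expect_warning(groups <- read_ndx(path), "empty")
  expect_equal(groups$heads, c(1L, 2L, 3L))
  expect_equal(groups$sel, c(4L, 5L))
  expect_equal(groups$sel_2, 9L)
  expect_equal(groups$empty, integer())
  # round trip
  path2 <- tempfile(fileext = ".ndx")
  write_ndx(groups[c("heads", "sel")], path2)
  expect_equal(read_ndx(path2), groups[c("heads", "sel")])
  # bounds checks
  writeLines(c("[ bad ]", "0 2"), path)
  expect_error(read_ndx(path), "1-based")
  writeLines(c("[ bad ]", "999"), path)
  expect_error(read_ndx(path, natoms = 10), "exceeds")
})

test_that("XVG writes re-parse to 6 significant digits", {
  df <- data.frame(frame = 0:1, apl = c(0.62, 0.64))
  path <- tempfile(fileext = ".xvg")
  write_xvg(df, path, title = "t", xlabel = "frame", ylabel = "APL")
  back <- read_xvg(path)
  expect_equal(back$apl, df$apl, tolerance = 1e-6)
  expect_equal(names(back), c("x", "apl"))
  expect_equal(attr(back, "title"), "t")
  # multi-column layout: x + one column per simulation
  df2 <- data.frame(frame = 0:2, simA = c(1, 2, 3) * 0.1,
                    simB = c(4, NA, 6) * 0.1)
  write_xvg(df2, path)
  back2 <- read_xvg(path)
  expect_equal(ncol(back2), 3)
  expect_true(is.na(back2$simB[[2]]))  # missing serialized as nan
  expect_equal(back2$simB[[3]], 0.6, tolerance = 1e-6)
  expect_error(write_xvg(data.frame(x = numeric()), path), "at least")
})

test_that("frame exports round-trip (txt and xml)", {
  res <- make_bilayer(nx = 2, ny = 2, spacing = 1, thickness = 4, seed = 9,
                      jitter_xy = 0.05)
  m <- compute_frame_metrics(res$frames[[1]], res$topology)
  tp <- tempfile(fileext = ".txt")
  xp <- tempfile(fileext = ".xml")
  write_frame_export(m, "txt", tp)
  write_frame_export(m, "xml", xp)
  expect_error(write_frame_export(m, "csv", tp), "txt")

  txt <- readLines(tp)
  expect_length(txt, 1 + 1 + nrow(m))  # comment + header + rows
  back_t <- read_frame_txt(tp)
  expect_equal(back_t$apl, m$apl)  # %.17g serialization is exact
  back_x <- read_frame_xml(xp)
  expect_equal(nrow(back_x), nrow(m))
  expect_identical(back_x$apl, m$apl)
  expect_identical(back_x$thickness, m$thickness)
  expect_equal(back_x$leaflet, as.character(m$leaflet))
  expect_equal(back_x$neighbor_profile, m$neighbor_profile,
               ignore_attr = TRUE)
})
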