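test_that("generated bilayers have the promised geometry and bookkeeping", {
  res <- make_bilayer(nx = 4, ny = 4, spacing = 1, thickness = 4, seed = 111)
  expect_equal(res$n_lipids, 32)
  expect_equal(res$natoms, 96)
  expect_equal(res$box[1:2], c(4, 4))
  expect_gte(res$box[[3]], 8)
  expect_equal(nrow(res$truth), 32)
  # per-leaflet APL after tessellation is the lattice cell, exactly
  m <- compute_frame_metrics(res$frames[[1]], res$topology)
  expect_equal(m$apl, rep(1, 32), tolerance = 1e-9)
  # NDX heads group points at the P atoms
  heads <- read_ndx(res$paths$ndx, natoms = res$natoms)$heads
  expect_equal(heads, res$topology$lipids$head)
})

test_that("inverted lipids are counted exactly and marked in the truth table", {
  res <- make_bilayer(nx = 10, ny = 10, spacing = 0.8, thickness = 4,
                      inverted_fraction = 0.1, seed = 112)
  inv <- res$truth$inverted
  expect_equal(sum(inv[res$truth$leaflet == "upper"]), 10)
  expect_equal(sum(inv[res$truth$leaflet == "lower"]), 10)
})

test_that("the same seed reproduces output files byte for byte", {
  d1 <- tempfile("s1"); d2 <- tempfile("s2")
  dir.create(d1); dir.create(d2)
  sp <- synth_spec(nx = 4, ny = 4, spacing = 1, thickness = 4,
                   jitter_xy = 0.05, jitter_z = 0.03, n_frames = 3,
                   seed = 113)
  a <- generate_bilayer(sp, file.path(d1, "bl"))
  b <- generate_bilayer(sp, file.path(d2, "bl"))
  for (f in c("pdb", "traj", "ndx", "truth")) {
    expect_identical(readBin(a$paths[[f]], "raw", file.size(a$paths[[f]])),
                     readBin(b$paths[[f]], "raw", file.size(b$paths[[f]])),
                     label = f)
  }
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_bilayer(sp, file.path(d2, "bl2")))
  expect_identical(runif(3), before)
})

test_that("generated files feed back through every reader", {
  res <- make_bilayer(nx = 3, ny = 3, spacing = 1.1, thickness = 3.6,
                      n_frames = 2, jitter_z = 0.02, seed = 114,
                      traj_format = "trr")
  expect_equal(length(res$frames), 2)
  expect_equal(res$frames[[2]]$box, res$box)
  # TRR is double precision: PDB-vs-TRR first-frame coordinates match to
  # PDB's 0.001 Angstrom print resolution
  ref <- reference_frame(res$topology)
  expect_lt(max(abs(ref$coords - res$frames[[1]]$coords)), 1e-4 / 2 + 1e-9)
  # XTC variant is quantized at 1e-4 nm
  resx <- make_bilayer(nx = 3, ny = 3, spacing = 1.1, thickness = 3.6,
                       jitter_z = 0.02, seed = 114)
  expect_lt(max(abs(resx$frames[[1]]$coords -
                      res$frames[[1]]$coords)), 1e-4)
  expect_error(synth_spec(nx = 1, ny = 2), "at least 4")
  expect_error(synth_spec(nx = 4, ny = 4, spacing = 0.5,
                          inclusion = list(radius = 2, n_atoms = 5)),
               "too small")
})

test_that("position-based detection recovers generator truth on curved bilayers", {
  res <- make_bilayer(nx = 8, ny = 8, spacing = 0.8, thickness = 4,
                      curvature = "quad_bulge", curvature_amplitude = 0.8,
                      seed = 115)
  a <- assign_by_position(res$frames[[1]], res$topology, 2)
  expect_equal(a$labels, res$truth$leaflet)
})
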