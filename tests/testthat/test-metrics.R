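test_that("lattice APL equals box_area / n exactly", {
  for (k in c(4, 8)) {
    spacing <- if (k == 4) 1 else 0.8
    g <- expand.grid(x = (seq_len(k) - 0.5) * spacing,
                     y = (seq_len(k) - 0.5) * spacing)
    gens <- data.frame(kind = "lipid", lipid_id = seq_len(k * k),
                       atom_id = seq_len(k * k), resname = "DPPC",
                       x = g$x, y = g$y, z = 2)
    tess <- tessellate_leaflet(gens, c(k, k) * spacing)
    apl <- compute_apl(tess)
    expect_equal(apl$apl, rep(spacing^2, k * k), tolerance = 1e-12)
  }
  # random configuration: the partition fixes the mean exactly
  box <- c(6, 7)
  tess <- tessellate_leaflet(random_generators(50, box, 71), box)
  expect_equal(mean(compute_apl(tess)$apl), box[[1]] * box[[2]] / 50,
               tolerance = 1e-12)
})

test_that("thickness is exact for flat and affine reference bilayers", {
  for (t in c(3, 4, 5)) {
    res <- make_bilayer(nx = 4, ny = 4, spacing = 1, thickness = t,
                        seed = 80 + t)
    m <- compute_thickness(res$frames[[1]], res$topology,
                           assign_by_orientation(res$frames[[1]],
                                                 res$topology))
    expect_equal(m$thickness, rep(t, 32), tolerance = 1e-12)
  }

  # tilt the lower leaflet: z_lower = z0 + 0.1 x; barycentric interpolation
  # reproduces the affine surface, so thickness matches the closed form
  res <- make_bilayer(nx = 5, ny = 5, spacing = 1, thickness = 4, seed = 85)
  fr <- res$frames[[1]]
  topo <- res$topology
  asg <- assign_by_orientation(fr, topo)
  lower_atoms <- which(!is.na(topo$atoms$lipid_id) &
                         topo$atoms$lipid_id %in%
                           topo$lipids$lipid_id[asg$labels == "lower"])
  fr$coords[lower_atoms, 3] <- fr$coords[lower_atoms, 3] +
    0.1 * fr$coords[lower_atoms, 1]
  th <- compute_thickness(fr, topo, asg)
  upper <- asg$labels == "upper"
  hx <- fr$coords[topo$lipids$head[upper], 1]
  hz <- fr$coords[topo$lipids$head[upper], 3]
  z_lower0 <- unique(round(fr$coords[topo$lipids$head[!upper], 3] -
                             0.1 * fr$coords[topo$lipids$head[!upper], 1], 9))
  expect_length(z_lower0, 1)
  closed_form <- abs(hz - (z_lower0 + 0.1 * hx))
  expect_equal(th$thickness[upper], closed_form, tolerance = 1e-10)
})

test_that("thickness symmetry holds on zero-jitter flat bilayers", {
  res <- make_bilayer(nx = 4, ny = 6, spacing = 0.9, thickness = 4.2,
                      seed = 90)
  th <- compute_thickness(res$frames[[1]], res$topology,
                          assign_by_orientation(res$frames[[1]],
                                                res$topology))
  up <- th$thickness[res$truth$leaflet == "upper"]
  lo <- th$thickness[res$truth$leaflet == "lower"]
  expect_equal(up, lo, tolerance = 1e-12)
})

test_that("jittered bilayer thickness stays near its nominal value", {
  res <- make_bilayer(nx = 16, ny = 16, spacing = 0.8, thickness = 4,
                      jitter_z = 0.05, seed = 91)
  fr <- res$frames[[1]]
  th <- compute_thickness(fr, res$topology,
                          assign_by_orientation(fr, res$topology))
  expect_true(all(abs(th$thickness - 4) < 0.3))
  expect_lt(abs(mean(th$thickness) - 4), 0.02)
})

test_that("barycentric interpolation reproduces random affine fields", {
  set.seed(92)
  x <- c(0, 6, 0, 6, runif(40, 0, 6))
  y <- c(0, 0, 6, 6, runif(40, 0, 6))
  del <- .Call(lipidvoro:::C_delaunay, x, y)
  for (rep in 1:5) {
    a <- rnorm(3)
    mesh <- list(tri = del$triangles, xy = cbind(x, y),
                 z = a[[1]] + a[[2]] * x + a[[3]] * y)
    qx <- runif(30, 0.2, 5.8)
    qy <- runif(30, 0.2, 5.8)
    zhat <- lipidvoro:::.interp_surface_z(mesh, qx, qy)
    expect_equal(zhat, a[[1]] + a[[2]] * qx + a[[3]] * qy, tolerance = 1e-10)
  }
})

test_that("neighbor profiles match construction and brute-force recount", {
  # two-species checkerboard: every neighbor is of the other species
  k <- 6
  g <- expand.grid(ix = seq_len(k) - 1L, iy = seq_len(k) - 1L)
  gens <- data.frame(kind = "lipid", lipid_id = seq_len(k * k),
                     atom_id = seq_len(k * k),
                     resname = ifelse((g$ix + g$iy) %% 2 == 0, "DPPC", "DOPC"),
                     x = g$ix + 0.5, y = g$iy + 0.5, z = 2)
  tess <- tessellate_leaflet(gens, c(k, k))
  prof <- neighbor_profile(tess)
  expect_equal(prof$n_neighbors, rep(4L, k * k))
  for (i in seq_len(k * k)) {
    other <- if (gens$resname[[i]] == "DPPC") "DOPC" else "DPPC"
    expect_equal(prof$neighbor_profile[[i]], setNames(4L, other))
  }

  # random mixed configuration: counts equal a recount over shared edges
  box <- c(6, 5)
  gens <- random_generators(30, box, 93)
  gens$resname <- rep(c("DPPC", "DOPC", "POPE"), each = 10)
  tess <- tessellate_leaflet(gens, box)
  prof <- neighbor_profile(tess)
  for (i in seq_len(30)) {
    nb <- tess$adjacency[[i]]
    expect_equal(sum(prof$neighbor_profile[[i]]), length(nb))
    recount <- table(gens$resname[nb])
    expect_equal(prof$neighbor_profile[[i]],
                 setNames(as.integer(recount), names(recount)))
  }
})

test_that("aggregation reduces per-lipid tables the way a manual mean does", {
  res <- make_bilayer(nx = 4, ny = 4, spacing = 1, thickness = 4,
                      n_frames = 3, jitter_xy = 0.04, jitter_z = 0.02,
                      seed = 94)
  ms <- lapply(res$frames, function(fr)
    compute_frame_metrics(fr, res$topology,
                          assign_by_position(fr, res$topology, 2)))
  ts <- aggregate_metrics(ms, "mean_apl")
  expect_equal(nrow(ts), 3)
  expect_equal(ts$mean_apl,
               vapply(ms, function(m) mean(m$apl), numeric(1)))
  # lattice bilayer: per-frame mean APL is pinned by the partition
  expect_equal(ts$mean_apl, rep(1, 3), tolerance = 1e-9)

  # selection of one lipid returns its own values
  one <- aggregate_metrics(ms, "mean_thickness", selection = 5L)
  expect_equal(one$mean_thickness,
               vapply(ms, function(m) m$thickness[m$lipid_id == 5L],
                      numeric(1)))
  # mean over the upper leaflet equals a manual recomputation
  up_ids <- ms[[1]]$lipid_id[ms[[1]]$leaflet == "upper"]
  up <- aggregate_metrics(ms, "mean_apl", selection = up_ids)
  expect_equal(up$mean_apl,
               vapply(ms, function(m) mean(m$apl[m$leaflet == "upper"]),
                      numeric(1)))
  expect_error(aggregate_metrics(ms, "median_apl"), "unknown statistic")
  expect_error(aggregate_metrics(ms, "mean_apl", selection = 999L),
               "unknown lipid")
})
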