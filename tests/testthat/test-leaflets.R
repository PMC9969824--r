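test_that("fit_midplane reproduces surfaces in its model class exactly", {
  set.seed(21)
  x <- runif(60, 0, 8)
  y <- runif(60, 0, 8)
  # constant surface, d = 0
  s0 <- fit_midplane(cbind(x, y, 1.5), 0)
  expect_lt(max(abs(eval_surface(s0, x, y) - 1.5)), 1e-9)
  expect_equal(s0$coeffs, 1.5, tolerance = 1e-12)
  # quadratic surface, d = 2
  z <- 1 + 0.1 * x + 0.05 * y^2
  s2 <- fit_midplane(cbind(x, y, z), 2)
  expect_lt(max(abs(eval_surface(s2, x, y) - z)), 1e-9)
})

test_that("fit_midplane matches the closed-form normal-equations oracle", {
  set.seed(22)
  n <- 400
  x <- runif(n, 0, 10)
  y <- runif(n, 0, 10)
  z <- 2 + rnorm(n, 0, 0.05)
  pts <- cbind(x, y, z)
  s1 <- fit_midplane(pts, 1)
  oracle <- ols_normal_equations(pts, 1)
  expect_equal(s1$coeffs, as.numeric(oracle), tolerance = 1e-8)
  # intercept of a noisy plane within 3 sigma / sqrt(n) of truth
  expect_lt(abs(s1$coeffs[[1]] - 2), 3 * 0.05 / sqrt(n))
  # residuals orthogonal to the design (normal equations hold)
  X <- lipidvoro:::.design_matrix(x, y, s1$powers)
  r <- z - eval_surface(s1, x, y)
  expect_lt(max(abs(t(X) %*% r)) / max(abs(t(X) %*% z)), 1e-8)
})

test_that("residual sum of squares never increases with degree", {
  set.seed(23)
  n <- 120
  x <- runif(n, 0, 6); y <- runif(n, 0, 6)
  z <- 0.5 + 0.05 * x - 0.02 * y + rnorm(n, 0, 0.1)
  rss <- vapply(0:4, function(d) {
    s <- fit_midplane(cbind(x, y, z), d)
    sum((z - eval_surface(s, x, y))^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("fit_midplane rejects underdetermined or degenerate designs", {
  expect_error(fit_midplane(cbind(1:3, 1:3, 1), 2), "underdetermined")
  # collinear xy points cannot support a planar fit
  x <- seq(0, 5, length.out = 20)
  expect_error(fit_midplane(cbind(x, 2 * x, 1), 1), "rank-deficient")
})

test_that("orientation rule follows the head-minus-tail sign", {
  # two-lipid toy frame built directly from a 2x2 synthetic bilayer
  res <- make_bilayer(nx = 2, ny = 2, spacing = 1.5, thickness = 4, seed = 31)
  fr <- res$frames[[1]]
  topo <- res$topology
  a <- assign_by_orientation(fr, topo)
  expect_equal(a$labels, res$truth$leaflet)
  expect_equal(a$method, "orientation")
  # flip one head below its tails -> label flips
  fr2 <- fr
  hd <- topo$lipids$head[[1]]
  tl <- topo$lipids$tails[[1]]
  fr2$coords[hd, 3] <- min(fr2$coords[tl, 3]) - 1
  a2 <- assign_by_orientation(fr2, topo)
  expect_equal(a2$labels[[1]], "lower")
  expect_equal(a2$labels[-1], a$labels[-1])
  # lipids without tails are refused
  topo_nt <- read_topology(res$paths$pdb,
                           list(lipid_def("DPPC", "P", "XX")))
  expect_error(assign_by_orientation(fr, topo_nt), "tail")
})

test_that("position method recovers flat, curved and adversarial bilayers", {
  flat <- make_bilayer(nx = 6, ny = 6, spacing = 0.8, thickness = 4,
                       seed = 32)
  a <- assign_by_position(flat$frames[[1]], flat$topology, degree = 0)
  expect_equal(a$labels, flat$truth$leaflet)
  expect_lt(abs(eval_surface(a$surface, 1, 1) - flat$box[[3]] / 2), 1e-9)

  curved <- make_bilayer(nx = 8, ny = 8, spacing = 0.8, thickness = 4,
                         curvature = "quad_bulge", curvature_amplitude = 0.8,
                         seed = 33)
  ac <- assign_by_position(curved$frames[[1]], curved$topology, degree = 2)
  expect_equal(ac$labels, curved$truth$leaflet)

  # 10% inverted lipids: position survives, orientation mislabels exactly them
  adv <- make_bilayer(nx = 10, ny = 10, spacing = 0.8, thickness = 4,
                      inverted_fraction = 0.1, seed = 34)
  fr <- adv$frames[[1]]
  ap <- assign_by_position(fr, adv$topology, degree = 2)
  expect_equal(ap$labels, adv$truth$leaflet)
  ao <- assign_by_orientation(fr, adv$topology)
  mis <- ao$labels != adv$truth$leaflet
  expect_equal(mis, adv$truth$inverted)
  expect_equal(sum(mis), 20)
})

test_that("position labels are invariant under rigid z translation", {
  res <- make_bilayer(nx = 5, ny = 5, spacing = 0.9, thickness = 3.5,
                      jitter_z = 0.05, jitter_xy = 0.05, seed = 35)
  fr <- res$frames[[1]]
  a1 <- assign_by_position(fr, res$topology, 2)
  fr$coords[, 3] <- fr$coords[, 3] + 13.7
  a2 <- assign_by_position(fr, res$topology, 2)
  expect_equal(a1$labels, a2$labels)
})

test_that("orientation and position agree on zero-jitter bilayers", {
  for (seed in c(41, 42)) {
    res <- make_bilayer(nx = 4, ny = 5, spacing = 1, thickness = 4,
                        seed = seed)
    fr <- res$frames[[1]]
    expect_equal(assign_by_orientation(fr, res$topology)$labels,
                 assign_by_position(fr, res$topology, 2)$labels)
  }
})
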