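test_that("replicate_periodic keeps primaries and the right images", {
  set.seed(51)
  pts <- cbind(runif(16, 0, 10), runif(16, 0, 10))
  # full replication: margin = max box length -> 9n points
  r <- replicate_periodic(pts, c(10, 10), 10)
  expect_equal(nrow(r$xy), 9 * 16)
  expect_equal(r$xy[1:16, ], pts)
  expect_false(any(r$is_image[1:16]))
  # small margin keeps only nearby images
  r2 <- replicate_periodic(rbind(c(0.1, 0.1)), c(10, 10), 1)
  expect_equal(nrow(r2$xy), 4)
  have <- apply(r2$xy, 1, paste, collapse = ",")
  expect_setequal(have, c("0.1,0.1", "10.1,0.1", "0.1,10.1", "10.1,10.1"))
  # primaries always retained
  r3 <- replicate_periodic(pts, c(10, 10), 0.25)
  expect_gte(nrow(r3$xy), 16)
  expect_equal(r3$source[1:16], 1:16)
  expect_error(replicate_periodic(pts, c(-1, 10), 1), "positive")
})

test_that("square lattices tessellate into exact unit cells", {
  for (k in c(3, 4, 7)) {
    g <- expand.grid(x = (seq_len(k) - 0.5), y = (seq_len(k) - 0.5))
    tess <- tessellate_leaflet(as.matrix(g), c(k, k))
    expect_equal(tess$areas, rep(1, k * k), tolerance = 1e-12)
    expect_equal(lengths(tess$adjacency), rep(4L, k * k))
    # neighbors are the four lattice neighbors (periodic)
    i <- 1L  # corner generator
    nb <- sort(tess$adjacency[[1]])
    expect_length(nb, 4)
  }
})

test_that("cell areas always partition the box", {
  for (seed in 1:12) {
    n <- sample(c(16, 50, 100), 1)
    box <- c(runif(1, 4, 12), runif(1, 4, 12))
    gens <- random_generators(n, box, seed)
    tess <- tessellate_leaflet(gens, box)
    expect_lt(abs(sum(tess$areas) - box[[1]] * box[[2]]),
              1e-8 * box[[1]] * box[[2]])
    expect_true(all(tess$areas > 0))
    expect_true(all(lengths(tess$adjacency) >= 3))
    # adjacency is symmetric
    adj <- adjacency_matrix(tess)
    expect_identical(adj, t(adj))
  }
})

test_that("tessellation is invariant under rigid translation modulo the box", {
  box <- c(7, 5)
  gens <- random_generators(40, box, 77)
  t0 <- tessellate_leaflet(gens, box)
  gens2 <- gens
  gens2$x <- gens2$x + 3.123
  gens2$y <- gens2$y - 1.789
  t1 <- tessellate_leaflet(gens2, box)
  expect_equal(t1$areas, t0$areas, tolerance = 1e-8)
  expect_identical(t1$adjacency, t0$adjacency)
})

test_that("2x2 tiling of the box reproduces every cell area four times", {
  box <- c(6, 6)
  gens <- random_generators(25, box, 99)
  t0 <- tessellate_leaflet(gens, box)
  tiled <- do.call(rbind, lapply(list(c(0, 0), c(6, 0), c(0, 6), c(6, 6)),
                                 function(s) cbind(gens$x + s[[1]],
                                                   gens$y + s[[2]])))
  t4 <- tessellate_leaflet(tiled, c(12, 12))
  expect_equal(sort(t4$areas), sort(rep(t0$areas, 4)), tolerance = 1e-8)
})

test_that("Delaunay circumcircles are empty and adjacency matches brute force", {
  for (seed in 1:6) {
    n <- sample(12:32, 1)
    box <- c(runif(1, 4, 8), runif(1, 4, 8))
    gens <- random_generators(n, box, seed + 500)
    tess <- tessellate_leaflet(gens, box)

    # empty-circumcircle property over all replicated points
    tri <- tess$triangles
    cc <- tess$circumcenters
    px <- tess$points[, 1]; py <- tess$points[, 2]
    primary <- tri[, 1] <= n | tri[, 2] <= n | tri[, 3] <= n
    for (t in which(primary)) {
      r2 <- (px[tri[t, 1]] - cc[t, 1])^2 + (py[tri[t, 1]] - cc[t, 2])^2
      d2 <- (px - cc[t, 1])^2 + (py - cc[t, 2])^2
      d2[tri[t, ]] <- Inf
      expect_gte(min(d2), r2 * (1 - 1e-9))
    }

    # adjacency equals the minimum-image bisector oracle
    claimed <- which(adjacency_matrix(tess), arr.ind = TRUE)
    oracle <- adjacency_oracle(as.matrix(gens[, c("x", "y")]), box, claimed)
    expect_identical(adjacency_matrix(tess), oracle)
  }
})

test_that("the Delaunay engine agrees with deldir on Euclidean point sets", {
  for (seed in c(131, 132, 133)) {
    set.seed(seed)
    n <- 60
    x <- runif(n); y <- runif(n)
    del <- .Call(lipidvoro:::C_delaunay, x, y)
    tri <- del$triangles
    mine <- unique(t(apply(cbind(c(tri[, 1], tri[, 2], tri[, 1]),
                                 c(tri[, 2], tri[, 3], tri[, 3])), 1, sort)))
    dd <- deldir::deldir(x, y)$delsgs
    theirs <- unique(cbind(pmin(dd$ind1, dd$ind2), pmax(dd$ind1, dd$ind2)))
    expect_setequal(paste(mine[, 1], mine[, 2]),
                    paste(theirs[, 1], theirs[, 2]))
  }
})

test_that("degenerate inputs are handled deterministically", {
  box <- c(5, 5)
  gens <- random_generators(12, box, 7)
  gens$x[[2]] <- gens$x[[1]]
  gens$y[[2]] <- gens$y[[1]]
  expect_warning(tess <- tessellate_leaflet(gens, box), "coincident")
  expect_lt(abs(sum(tess$areas) - 25), 1e-8 * 25)
  expect_error(tessellate_leaflet(gens[1:2, ], box), "at least 3")
})

test_that("inclusion atoms become extra generators within the leaflet slab", {
  res <- make_bilayer(nx = 6, ny = 6, spacing = 1, thickness = 4,
                      inclusion = list(radius = 1.2, n_atoms = 12),
                      seed = 61)
  fr <- res$frames[[1]]
  topo <- res$topology
  asg <- assign_by_position(fr, topo, 0)
  # no non-lipid residues -> generator list unchanged
  flat <- make_bilayer(nx = 4, ny = 4, spacing = 1, thickness = 4, seed = 62)
  g0 <- lipid_generators(flat$frames[[1]], flat$topology,
                         assign_by_position(flat$frames[[1]], flat$topology, 0),
                         "upper")
  g1 <- insert_inclusions(flat$frames[[1]], flat$topology,
                          assign_by_position(flat$frames[[1]], flat$topology, 0),
                          "upper")
  expect_identical(g0, g1)

  for (lf in c("upper", "lower")) {
    gens <- insert_inclusions(fr, topo, asg, lf, slab_margin = 0.5)
    # expected count from generator bookkeeping: PROT atoms inside the slab
    prot <- which(is.na(topo$atoms$lipid_id))
    heads <- topo$lipids$head[asg$labels == lf]
    zr <- range(fr$coords[heads, 3])
    expected <- sum(fr$coords[prot, 3] >= zr[[1]] - 0.5 &
                      fr$coords[prot, 3] <= zr[[2]] + 0.5)
    expect_gt(expected, 0)
    expect_equal(sum(gens$kind == "inclusion"), expected)
    # partition still exact; lipid share strictly below the box area
    tess <- tessellate_leaflet(gens, res$box[1:2])
    box_area <- res$box[[1]] * res$box[[2]]
    expect_lt(abs(sum(tess$areas) - box_area), 1e-8 * box_area)
    expect_lt(sum(tess$areas[tess$generators$kind == "lipid"]), box_area)
  }
})
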