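# Shared fixtures and independent oracles.

# squared minimum-image distance in the xy plane
mi_dist2 <- function(px, py, qx, qy, box) {
  dx <- abs(px - qx)
  dx <- pmin(dx, box[[1]] - dx)
  dy <- abs(py - qy)
  dy <- pmin(dy, box[[2]] - dy)
  dx * dx + dy * dy
}

# owner of each point under the minimum-image nearest-generator rule
mi_owner <- function(sx, sy, gens, box) {
  best <- rep.int(1L, length(sx))
  bestd <- mi_dist2(sx, sy, gens[1, 1], gens[1, 2], box)
  for (g in seq_len(nrow(gens))[-1]) {
    d2 <- mi_dist2(sx, sy, gens[g, 1], gens[g, 2], box)
    upd <- d2 < bestd
    best[upd] <- g
    bestd[upd] <- d2[upd]
  }
  best
}

# Does some point of the plane see generators i and j as its two nearest
# (under the minimum-image metric)? Sampled along the Euclidean bisector of
# i and each periodic image of j.
pair_shares_edge <- function(i, j, gens, box, nsamp = 2048) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1))
  tgrid <- seq(-max(box) / 2, max(box) / 2, length.out = nsamp)
  others <- setdiff(seq_len(nrow(gens)), c(i, j))
  probe <- function(mid, perp, ts) {
    sx <- mid[[1]] + ts * perp[[1]]
    sy <- mid[[2]] + ts * perp[[2]]
    di <- sqrt(mi_dist2(sx, sy, gens[i, 1], gens[i, 2], box))
    dj <- sqrt(mi_dist2(sx, sy, gens[j, 1], gens[j, 2], box))
    dmin_other <- rep(Inf, length(ts))
    for (k in others) {
      dk <- sqrt(mi_dist2(sx, sy, gens[k, 1], gens[k, 2], box))
      dmin_other <- pmin(dmin_other, dk)
    }
    # negative where {i, j} are strictly the two nearest (a Voronoi edge)
    ifelse(abs(di - dj) < 1e-7, pmax(di, dj) - dmin_other, Inf)
  }
  for (s in seq_len(nrow(shifts))) {
    q <- gens[j, 1:2] + shifts[s, ] * box
    dvec <- q - gens[i, 1:2]
    nd <- sqrt(sum(dvec^2))
    if (nd < 1e-12) next
    mid <- (gens[i, 1:2] + q) / 2
    perp <- c(-dvec[[2]], dvec[[1]]) / nd
    f <- probe(mid, perp, tgrid)
    if (any(f < -1e-9)) return(TRUE)
    # refine around the most promising point: short Voronoi edges can fall
    # between coarse samples
    t0 <- tgrid[[which.min(f)]]
    step <- tgrid[[2]] - tgrid[[1]]
    fine <- probe(mid, perp, seq(t0 - 2 * step, t0 + 2 * step,
                                 length.out = nsamp))
    if (any(fine < -1e-9)) return(TRUE)
  }
  FALSE
}

# Brute-force periodic Voronoi adjacency: grid scan for candidates, then a
# bisector check decides every candidate and every disputed pair.
adjacency_oracle <- function(gens, box, claimed, grid = 400L) {
  n <- nrow(gens)
  sx <- (seq_len(grid) - 0.5) / grid * box[[1]]
  sy <- (seq_len(grid) - 0.5) / grid * box[[2]]
  px <- rep(sx, times = grid)
  py <- rep(sy, each = grid)
  own <- matrix(mi_owner(px, py, gens, box), grid, grid)
  cand <- unique(rbind(
    cbind(as.vector(own[-grid, ]), as.vector(own[-1, ])),
    cbind(as.vector(own[, -grid]), as.vector(own[, -1])),
    # wrap-around neighbors across the periodic boundary
    cbind(own[grid, ], own[1, ]), cbind(own[, grid], own[, 1])))
  cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  key <- paste(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
  cand <- cand[!duplicated(key), , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  check <- rbind(cand, claimed)
  key <- paste(pmin(check[, 1], check[, 2]), pmax(check[, 1], check[, 2]))
  check <- check[!duplicated(key), , drop = FALSE]
  for (r in seq_len(nrow(check))) {
    i <- check[r, 1]; j <- check[r, 2]
    if (i == j) next
    if (pair_shares_edge(i, j, gens, box)) {
      adj[i, j] <- TRUE
      adj[j, i] <- TRUE
    }
  }
  adj
}

adjacency_matrix <- function(tess) {
  n <- nrow(tess$generators)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, tess$adjacency[[i]]] <- TRUE
  adj
}

# closed-form OLS via normal equations (independent of fit_midplane's QR)
ols_normal_equations <- function(points, degree) {
  pw <- expand.grid(a = 0:degree, b = 0:degree)
  pw <- pw[pw$a + pw$b <= degree, ]
  pw <- pw[order(pw$a + pw$b, pw$a), ]
  X <- sapply(seq_len(nrow(pw)),
              function(j) points[, 1]^pw$a[[j]] * points[, 2]^pw$b[[j]])
  solve(t(X) %*% X, t(X) %*% points[, 3])
}

# random generator layout in a box
random_generators <- function(n, box, seed) {
  set.seed(seed)
  data.frame(kind = "lipid", lipid_id = seq_len(n), atom_id = seq_len(n),
             resname = "DPPC", x = runif(n, 0, box[[1]]),
             y = runif(n, 0, box[[2]]), z = 2,
             stringsAsFactors = FALSE)
}

# synthetic bilayer in a fresh tempdir; returns generate_bilayer()'s result
# plus the loaded topology and first frame
make_bilayer <- function(..., traj_format = "xtc") {
  prefix <- file.path(tempfile("synth"), "bl")
  dir.create(dirname(prefix))
  res <- generate_bilayer(synth_spec(...), prefix, traj_format = traj_format)
  res$topology <- read_topology(res$paths$pdb)
  res$frames <- read_trajectory(res$paths$traj, res$topology)
  res
}
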