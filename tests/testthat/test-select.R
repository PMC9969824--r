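test_that("the query grammar parses and rejects as documented", {
  q <- parse_query("resname == DPPC and apl > 0.6")
  expect_length(q$conditions, 2)
  expect_equal(q$conditions[[1]]$field, "resname")
  expect_equal(q$conditions[[2]]$op, ">")
  expect_equal(q$conditions[[2]]$value, 0.6)

  q1 <- parse_query("thickness >= 3.5")
  expect_length(q1$conditions, 1)

  qn <- parse_query("neighbor_count[DOPC] >= 2 and leaflet == upper")
  expect_equal(qn$conditions[[1]]$subfield, "DOPC")

  qin <- parse_query("resname in (DPPC, DOPC)")
  expect_equal(qin$conditions[[1]]$value, c("DPPC", "DOPC"))

  expect_error(parse_query("apl >> 1"), "character")
  expect_error(parse_query("apl >"), "unexpected end")
  expect_error(parse_query("banana > 1"), "unknown selection field")
  expect_error(parse_query("resname < DPPC"), "categorical")
  expect_error(parse_query(""), "empty")
})

test_that("selections evaluate like a brute-force row filter", {
  res <- make_bilayer(nx = 6, ny = 6, spacing = 0.85, thickness = 4,
                      jitter_xy = 0.06, jitter_z = 0.04, seed = 101)
  m <- compute_frame_metrics(res$frames[[1]], res$topology,
                             assign_by_position(res$frames[[1]],
                                                res$topology, 2))
  # apl > 0 selects everything (positivity invariant)
  expect_setequal(evaluate_selection(m, "apl > 0"), m$lipid_id)

  q <- "leaflet == upper and apl > 0.7 and thickness <= 4.05"
  got <- evaluate_selection(m, q)
  want <- m$lipid_id[m$leaflet == "upper" & m$apl > 0.7 &
                       m$thickness <= 4.05]
  expect_setequal(got, want)

  qn <- evaluate_selection(m, "neighbor_count[DPPC] >= 6")
  wantn <- m$lipid_id[vapply(m$neighbor_profile, function(p)
    isTRUE(p["DPPC"] >= 6), logical(1))]
  expect_setequal(qn, wantn)

  expect_error(evaluate_selection(m, "resname == POPG"), "unknown resname")
})

test_that("perfect lattices admit no lipid above the mean APL", {
  res <- make_bilayer(nx = 5, ny = 5, spacing = 1, thickness = 4, seed = 102)
  m <- compute_frame_metrics(res$frames[[1]], res$topology)
  # every APL equals box_area / n; a strict threshold at that value is empty
  expect_length(evaluate_selection(m, "resname == DPPC and apl > 1.0000001"),
                0)
})

test_that("conjunction is monotone and equals the intersection", {
  res <- make_bilayer(nx = 6, ny = 5, spacing = 0.9, thickness = 4,
                      jitter_xy = 0.05, seed = 103)
  m <- compute_frame_metrics(res$frames[[1]], res$topology)
  conds <- c("apl > 0.75", "leaflet == lower", "neighbors >= 6")
  sel <- list()
  prev <- m$lipid_id
  for (k in seq_along(conds)) {
    q <- paste(conds[seq_len(k)], collapse = " and ")
    cur <- evaluate_selection(m, q)
    expect_true(all(cur %in% prev))  # adding conditions never grows the set
    prev <- cur
    sel[[k]] <- evaluate_selection(m, conds[[k]])
  }
  expect_setequal(prev, Reduce(intersect, sel))
})
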