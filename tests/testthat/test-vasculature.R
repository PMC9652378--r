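test_that("perfusion demand is the exact linear tissue mixture", {
  ph <- fx_phantom()
  v_ml <- prod(ph$grid$voxel_size) / 1e3
  dem <- cbf_map_from_tpm(ph, cbf_gm = 60, cbf_wm = 22, tissue_density = 1.045)
  pure_gm <- 60 / 100 * 1.045 * v_ml
  pure_wm <- 22 / 100 * 1.045 * v_ml

  blk <- uniform_gm_block(10, ph$grid$voxel_size[1])
  expect_equal(unique(as.numeric(cbf_map_from_tpm(blk)$demand)), pure_gm)

  half <- blk
  half$tpm_gm[] <- 0.5; half$tpm_wm[] <- 0.5
  expect_equal(unique(as.numeric(cbf_map_from_tpm(half)$demand)),
               (pure_gm + pure_wm) / 2)

  csf <- blk
  csf$tpm_gm[] <- 0; csf$tpm_csf[] <- 1
  expect_equal(sum(cbf_map_from_tpm(csf)$demand), 0)
  expect_true(all(dem$demand[ph$tpm_gm + ph$tpm_wm == 0] == 0))
})

test_that("RRT augmentation is deterministic and adds the requested terminals", {
  ph <- fx_phantom()
  dem <- cbf_map_from_tpm(ph)
  seeds <- make_vessel_seeds(ph, 1L)
  t1 <- rrt_augment(seeds, dem, n_terminals = 30, seed = 5L)
  t2 <- rrt_augment(seeds, dem, n_terminals = 30, seed = 5L)
  expect_identical(t1$nodes, t2$nodes)
  # all requested terminals were placed (demand is reachable)
  expect_equal(unname(attr(t1, "shortfall")), c(0L, 0L))
  expect_gte(nrow(t1$nodes) - nrow(seeds$nodes), 60)
  expect_silent(validate_vessel_tree(t1, ph$grid))
})

test_that("RRT growth concentrates where the demand is", {
  ph <- fx_phantom20()
  dem <- cbf_map_from_tpm(ph)
  oct <- dem
  oct$demand[, , ] <- 0
  oct$demand[1:10, 1:10, 1:10] <- dem$demand[1:10, 1:10, 1:10]
  fr <- vapply(1:20, function(s) {
    tr <- rrt_augment(make_vessel_seeds(ph, s), oct, n_terminals = 30, seed = s)
    term <- tr$nodes[tr$nodes$id %in% brainheat:::tree_terminals(tr, "arterial"), ]
    v <- world_to_voxel(ph$grid, as.matrix(term[, c("x", "y", "z")]))
    mean(v[, 1] < 10 & v[, 2] < 10 & v[, 3] < 10)
  }, numeric(1))
  expect_gte(mean(fr), 0.8)

  # terminal density tracks demand on a two-level phantom (rank correlation)
  tr <- rrt_augment(make_vessel_seeds(ph, 1L), dem, n_terminals = 120, seed = 2L)
  term <- tr$nodes[tr$nodes$id %in% brainheat:::tree_terminals(tr, "arterial"), ]
  lin <- containing_voxel(ph$grid, as.matrix(term[, c("x", "y", "z")]))
  counts <- tabulate(lin, nbins = prod(ph$grid$shape))
  # compare per-region terminal counts with per-region demand
  reg <- as.integer(cut(seq_len(prod(ph$grid$shape)) - 1, 8))
  reg_counts <- tapply(counts, reg, sum)
  reg_dem <- tapply(as.numeric(dem$demand), reg, sum)
  expect_gt(cor(reg_counts, reg_dem, method = "spearman"), 0.5)
})

test_that("Murray's law yields 7 um terminals and the closed-form bifurcation ratio", {
  ph <- fx_phantom()
  dem <- cbf_map_from_tpm(ph)
  tr <- assign_radii(rrt_augment(make_vessel_seeds(ph, 1L), dem,
                                 n_terminals = 40, seed = 1L))
  n <- tr$nodes
  term_ids <- c(brainheat:::tree_terminals(tr, "arterial"),
                brainheat:::tree_terminals(tr, "venous"))
  expect_equal(unique(2 * n$radius_um[n$id %in% term_ids]), 7)
  # radii never increase from root to leaf
  pidx <- match(n$parent, n$id)
  seg <- !is.na(pidx)
  expect_true(all(n$radius_um[seg] <= n$radius_um[pidx[seg]] + 1e-9))

  # hand-built symmetric bifurcation and unbranched chain
  chain <- vessel_tree(data.frame(
    id = 1:4, x = c(0, 0, -5, 5), y = c(0, 0, 3, 3), z = c(0, 5, 9, 9),
    radius_um = 1, side = "arterial", parent = c(NA, 1L, 2L, 2L)))
  chain$nodes <- rbind(chain$nodes,
                       data.frame(id = 11, x = 0, y = 20, z = 0, radius_um = 1,
                                  side = "venous", parent = NA))
  out <- assign_radii(chain)$nodes
  expect_equal(out$radius_um[out$id == 3], 3.5)
  expect_equal(out$radius_um[out$id == 2], 2^(1 / 3) * 3.5)  # Murray closed form
  expect_equal(out$radius_um[out$id == 1], out$radius_um[out$id == 2])  # chain
})

test_that("flow distribution conserves mass exactly at every node", {
  ph <- fx_phantom()
  dem <- cbf_map_from_tpm(ph)
  tr <- assign_radii(rrt_augment(make_vessel_seeds(ph, 1L), dem,
                                 n_terminals = 50, seed = 1L))
  fl <- solve_flows(tr, dem)
  n <- tr$nodes
  flows <- fl$flows$flow_mLmin
  total_oracle <- sum(dem$demand)  # independent summation
  for (s in c("arterial", "venous")) {
    root <- n$id[is.na(n$parent) & n$side == s]
    expect_equal(flows[fl$flows$id == root], total_oracle,
                 tolerance = 1e-12)
  }
  # node balance: flow into every internal node equals the sum over children
  # plus its own terminal delivery
  va <- fl$voxel_assignment
  term_col <- c(arterial = "arterial_terminal", venous = "venous_terminal")
  for (s in c("arterial", "venous")) {
    for (id in n$id[n$side == s]) {
      kids <- n$id[!is.na(n$parent) & n$parent == id & n$side == s]
      own <- sum(va$demand_mLmin[va[[term_col[[s]]]] == id])
      inflow <- flows[fl$flows$id == id]
      outflow <- sum(flows[fl$flows$id %in% kids]) + own
      expect_lt(abs(inflow - outflow), 1e-12 * max(inflow, 1e-300))
    }
  }
  expect_true(all(flows >= 0))

  # linearity: doubling demand doubles every flow
  dem2 <- dem; dem2$demand <- dem$demand * 2
  fl2 <- solve_flows(tr, dem2)
  expect_equal(fl2$flows$flow_mLmin, 2 * flows, tolerance = 1e-12)

  dem0 <- dem; dem0$demand[] <- 0
  expect_warning(fl0 <- solve_flows(tr, dem0), "zero")
  expect_true(all(fl0$flows$flow_mLmin == 0))
})

test_that("SWC serialization round-trips the tree", {
  ph <- fx_phantom()
  tr <- make_vessel_seeds(ph, 2L)
  f <- tempfile(fileext = ".swc")
  write_swc(tr, f)
  back <- read_swc(f)
  expect_equal(back$nodes$x, tr$nodes$x, tolerance = 1e-5)
  expect_identical(back$nodes$side, tr$nodes$side)
  expect_identical(is.na(back$nodes$parent), is.na(tr$nodes$parent))
})
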