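test_that("inlet temperature follows the fixed and pulmonary-artery rules", {
  expect_equal(inlet_temperature(boundary_conditions()), 36.8)
  expect_equal(inlet_temperature(boundary_conditions("axillary",
                                                     axillary_temp = 36.33)),
               36.80)
  expect_equal(inlet_temperature(boundary_conditions("axillary",
                                                     axillary_temp = 37.0)),
               37.47)
  expect_error(inlet_temperature(boundary_conditions("axillary")), "axillary")
})

test_that("voxel properties are the exact TPM mixture of the class table", {
  tab <- thermal_properties()
  blk <- uniform_gm_block(10, 5)
  blk$tpm_gm[] <- 0; blk$tpm_wm[] <- 1  # pure WM
  pr <- voxel_properties(blk, tab)
  expect_equal(unique(as.numeric(pr$conductivity)), tab$wm$conductivity)
  expect_equal(unique(as.numeric(pr$metabolic)), tab$wm$metabolic)

  # linear in the fractions
  mixed <- blk
  mixed$tpm_gm[] <- 0.3; mixed$tpm_wm[] <- 0.7
  pm <- voxel_properties(mixed, tab)
  expect_equal(unique(as.numeric(pm$density)),
               0.3 * tab$gm$density + 0.7 * tab$wm$density)

  # total metabolic power against a 3-voxel hand summation
  tri <- blk
  tri$tpm_gm[] <- 0; tri$tpm_wm[] <- 0; tri$tpm_csf[] <- 0
  tri$tpm_gm[1, 1, 1] <- 1
  tri$tpm_wm[2, 1, 1] <- 1
  tri$tpm_gm[3, 1, 1] <- 0.5; tri$tpm_wm[3, 1, 1] <- 0.5
  pt <- voxel_properties(tri, tab)
  v_m3 <- prod(tri$grid$voxel_size) * 1e-9
  hand <- (16700 + 4175 + (16700 + 4175) / 2) * v_m3
  expect_equal(sum(pt$metabolic[pt$mask]) * v_m3, hand)
})

test_that("interior conduction rows are pure temperature differences", {
  blk <- uniform_gm_block(8, 5)
  blk$tpm_gm[] <- 0; blk$tpm_csf[] <- 1  # no metabolism, no perfusion
  pr <- voxel_properties(blk, thermal_properties())
  sys <- assemble_system(pr, boundary_conditions(scalp_mode = "adiabatic"))
  rs <- Matrix::rowSums(sys$A)
  expect_lt(max(abs(rs)), 1e-10)
})

test_that("a single voxel fed by one terminal matches the hand-derived balance", {
  # one perfused voxel; arterial root -> terminal, venous terminal -> root;
  # nodes placed outside the tissue voxel so no wall exchange couples them.
  shape <- c(8L, 8L, 8L)
  blk <- structure(list(grid = voxel_grid(shape, 5),
                        tpm_gm = array(0, shape), tpm_wm = array(0, shape),
                        tpm_csf = array(0, shape), labels = array(0L, shape),
                        roi_table = phantom_roi_table()),
                   class = "tissue_phantom")
  blk$tpm_gm[4, 4, 4] <- 1
  tab <- thermal_properties()
  pr <- voxel_properties(blk, tab)
  dem <- cbf_map_from_tpm(blk)
  co <- voxel_to_world(blk$grid, rbind(c(3, 3, 3), c(3, 3, 2), c(4, 3, 3), c(4, 3, 2)))
  tree <- vessel_tree(data.frame(
    id = 1:4,
    x = co[, 1], y = co[, 2], z = co[, 3],
    radius_um = c(100, 3.5, 3.5, 100),
    side = c("arterial", "arterial", "venous", "venous"),
    parent = c(NA, 1L, 4L, NA)))
  fl <- solve_flows(tree, dem)
  bc <- boundary_conditions(inlet_temp = 36.8, scalp_mode = "adiabatic")
  sys <- assemble_system(pr, bc, demand = dem, tree = tree, flows = fl,
                         blood = tab$blood)
  f <- solve_temperature(sys)
  # hand algebra: T_art_term = T_in; voxel: m c (T_in - T) + q V = 0
  m_kgs <- sum(dem$demand) * (tab$blood$density / 1e3) / 1e3 / 60
  v_m3 <- prod(blk$grid$voxel_size) * 1e-9
  t_hand <- 36.8 + tab$gm$metabolic * v_m3 / (m_kgs * tab$blood$specific_heat)
  expect_equal(f$tissue[4, 4, 4], t_hand, tolerance = 1e-10)
  # venous chain carries the tissue temperature to the outlet
  expect_equal(f$vessels$temperature[f$vessels$id == 4], t_hand,
               tolerance = 1e-10)
})

test_that("zero metabolism under an adiabatic boundary equilibrates at the inlet", {
  tab <- thermal_properties(gm = list(density = 1045, specific_heat = 3696,
                                      conductivity = 0.57, metabolic = 0))
  blk <- uniform_gm_block(10, 5)
  pr <- voxel_properties(blk, tab)
  dem <- cbf_map_from_tpm(blk)
  sys <- assemble_system(pr, boundary_conditions(scalp_mode = "adiabatic"),
                         demand = dem, blood = tab$blood)
  f <- solve_temperature(sys)
  expect_equal(range(f$tissue), c(36.8, 36.8), tolerance = 1e-12)
  aud <- energy_audit(f, sys)
  expect_equal(aud$venous_out_C, 36.8, tolerance = 1e-12)
})

test_that("uniform perfused tissue matches the closed-form perfusion balance", {
  blk <- uniform_gm_block(10, 5)
  tab <- thermal_properties()
  pr <- voxel_properties(blk, tab)
  dem <- cbf_map_from_tpm(blk, cbf_gm = 60, tissue_density = 1.045)
  sys <- assemble_system(pr, boundary_conditions(scalp_mode = "adiabatic"),
                         demand = dem, blood = tab$blood)
  f <- solve_temperature(sys)
  # closed form: dT = q / (w rho_b c_b), w = CBF * rho_tissue in 1/s
  w <- 60e-6 / (0.1 * 60) * 1045
  dt_ref <- tab$gm$metabolic / (w * tab$blood$density * tab$blood$specific_heat)
  expect_lt(max(abs(f$tissue - 36.8 - dt_ref)) / dt_ref, 0.01)
})

test_that("the field responds affinely to inlet and source changes", {
  ph <- fx_phantom20()
  base <- simulate_brain_temperature(ph, boundary_conditions(scalp_mode = "adiabatic"),
                                     n_terminals = 60, seed = 1L)
  up <- simulate_brain_temperature(ph, boundary_conditions(inlet_temp = 37.3,
                                                           scalp_mode = "adiabatic"),
                                   n_terminals = 60, seed = 1L)
  dd <- up$field$tissue - base$field$tissue
  expect_equal(range(dd, na.rm = TRUE), c(0.5, 0.5), tolerance = 1e-9)
  # gradients unchanged: the shifted field is a pure translation
  expect_lt(max(abs(dd - 0.5), na.rm = TRUE), 1e-9)

  # maximum principle under adiabatic boundary: bounded below by the inlet
  expect_gte(min(base$field$tissue, na.rm = TRUE), 36.8 - 1e-9)
  expect_gte(min(base$field$vessels$temperature), 36.8 - 1e-9)
})

test_that("energy is conserved and the venous outlet runs warmer than the inlet", {
  sim <- fx_sim()
  expect_lt(sim$audit$relative_imbalance, 1e-6)
  expect_lt(sim$field$residual, 1e-8)
  expect_gt(sim$audit$venous_out_C, sim$audit$arterial_in_C)
  # subcortical warmer than cortical with a robin scalp below body temperature
  ph <- fx_phantom20()
  reg <- regional_stats(sim$field$tissue, ph)
  cls <- tapply(reg$mean, reg$class, mean)
  expect_gt(cls[["subcortical"]], cls[["cortical"]])
})

test_that("conduction discretization is consistent under mesh refinement", {
  tab <- thermal_properties()
  mean_t <- vapply(c(8L, 16L), function(n) {
    blk <- uniform_gm_block(n, 40 / n)  # same 40 mm physical block
    pr <- voxel_properties(blk, tab)
    dem <- cbf_map_from_tpm(blk)
    sys <- assemble_system(pr, boundary_conditions(), demand = dem,
                           blood = tab$blood)
    mean(solve_temperature(sys)$tissue)
  }, numeric(1))
  expect_lt(abs(mean_t[2] - mean_t[1]) / abs(mean_t[1] - 24), 0.01)
})
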