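#' Thermophysical property table
#'
#' Per tissue class (GM, WM, CSF) and for blood: density (kg/m^3), specific
#' heat (J/kg/K), thermal conductivity (W/m/K) and volumetric metabolic heat
#' rate (W/m^3; zero for CSF and blood). Defaults are standard literature
#' values for human brain tissue; every entry is configurable.
#'
#' @param gm,wm,csf,blood named lists with entries `density`,
#'   `specific_heat`, `conductivity`, `metabolic`.
#' @return a `thermal_properties` list.
#' @export
thermal_properties <- function(
    gm = list(density = 1045, specific_heat = 3696, conductivity = 0.57, metabolic = 16700),
    wm = list(density = 1041, specific_heat = 3583, conductivity = 0.50, metabolic = 4175),
    csf = list(density = 1007, specific_heat = 4096, conductivity = 0.60, metabolic = 0),
    blood = list(density = 1050, specific_heat = 3800, conductivity = 0.52, metabolic = 0)) {
  tab <- list(gm = gm, wm = wm, csf = csf, blood = blood)
  for (cls in names(tab)) {
    v <- unlist(tab[[cls]][c("density", "specific_heat", "conductivity")])
    if (any(v <= 0)) stop("density/specific heat/conductivity must be positive")
    if (tab[[cls]]$metabolic < 0) stop("metabolic rates must be >= 0")
  }
  structure(tab, class = "thermal_properties")
}

#' Thermal boundary conditions
#'
#' The arterial inlet is either fixed (default 36.8 degrees C, the median of
#' published carotid [36.6] and brain tissue [37.0] temperatures) or derived
#' from a subject's axillary reading via the pulmonary-artery relationship
#' T_PA = T_ax + 0.47 degrees C. The scalp surface is either adiabatic or a
#' Robin (convective) boundary exchanging heat with the ambient air.
#'
#' @param inlet_mode "fixed" or "axillary".
#' @param inlet_temp fixed-mode inlet temperature, degrees C.
#' @param axillary_temp axillary reading, degrees C (required in axillary mode).
#' @param scalp_mode "robin" or "adiabatic".
#' @param ambient_temp ambient temperature, degrees C (robin mode).
#' @param surface_coefficient surface heat transfer coefficient, W/m^2/K.
#' @return a `boundary_conditions` list.
#' @export
boundary_conditions <- function(inlet_mode = c("fixed", "axillary"),
                                inlet_temp = 36.8, axillary_temp = NULL,
                                scalp_mode = c("robin", "adiabatic"),
                                ambient_temp = 24, surface_coefficient = 4) {
  inlet_mode <- match.arg(inlet_mode)
  scalp_mode <- match.arg(scalp_mode)
  if (scalp_mode == "robin" &&
      (is.null(ambient_temp) || is.null(surface_coefficient)))
    stop("robin scalp mode requires `ambient_temp` and `surface_coefficient`")
  structure(list(inlet_mode = inlet_mode, inlet_temp = inlet_temp,
                 axillary_temp = axillary_temp, scalp_mode = scalp_mode,
                 ambient_temp = ambient_temp,
                 surface_coefficient = surface_coefficient),
            class = "boundary_conditions")
}

#' Inlet arterial temperature implied by the boundary conditions
#'
#' Fixed mode returns `inlet_temp`; axillary mode returns
#' `axillary_temp + 0.47` (the pulmonary-artery conversion).
#' @param bc a [boundary_conditions()].
#' @return inlet temperature, degrees C.
#' @export
inlet_temperature <- function(bc) {
  if (bc$inlet_mode == "fixed") return(bc$inlet_temp)
  if (is.null(bc$axillary_temp) || is.na(bc$axillary_temp))
    stop("axillary inlet mode requires an axillary temperature reading")
  bc$axillary_temp + 0.47
}

#' Voxel-wise thermophysical properties from tissue probability maps
#'
#' Each property is the TPM-fraction-weighted mixture of the class values,
#' renormalized by the total tissue+CSF fraction so that a pure-WM voxel
#' gets the WM values exactly. Voxels with no tissue at all are excluded
#' from the solve.
#'
#' @param phantom a `tissue_phantom`.
#' @param table a [thermal_properties()].
#' @return a `voxel_properties` list: grid, mask, and 3-D arrays `density`,
#'   `specific_heat`, `conductivity`, `metabolic` (SI units).
#' @export
voxel_properties <- function(phantom, table = thermal_properties()) {
  tot <- phantom$tpm_gm + phantom$tpm_wm + phantom$tpm_csf
  mask <- tot > 0
  mix <- function(fld) {
    out <- array(0, phantom$grid$shape)
    out[mask] <- (phantom$tpm_gm[mask] * table$gm[[fld]] +
                  phantom$tpm_wm[mask] * table$wm[[fld]] +
                  phantom$tpm_csf[mask] * table$csf[[fld]]) / tot[mask]
    out
  }
  structure(list(grid = phantom$grid, mask = mask,
                 density = mix("density"), specific_heat = mix("specific_heat"),
                 conductivity = mix("conductivity"), metabolic = mix("metabolic")),
            class = "voxel_properties")
}

#' Assemble the steady-state conservative thermal system
#'
#' Finite-volume discretization with unknowns at every in-mask voxel plus
#' (when a vessel tree is supplied) every vessel node. Tissue voxel balance:
#' 6-neighbour conduction with harmonic-mean face conductivity, metabolic
#' source, optional Robin surface exchange on faces adjoining non-tissue,
#' and perfusion coupling. With a tree, each perfused voxel receives
#' capillary blood at its assigned arterial terminal's temperature and
#' returns it at tissue temperature to its assigned venous terminal; vessel
#' nodes carry upwind advection plus wall heat exchange with their
#' containing voxel using a constant-Nusselt laminar closure
#' (h = Nu k_blood / D). Without a tree, perfused voxels exchange with blood
#' at the inlet temperature (classical perfusion sink). Every interior
#' equation is a pure difference of temperatures, so mass and energy
#' conservation are structural.
#'
#' @param props a [voxel_properties()].
#' @param bc a [boundary_conditions()].
#' @param demand optional `perfusion_demand` (enables perfusion coupling).
#' @param tree optional `vessel_tree` with radii assigned.
#' @param flows optional `flow_solution` matching `tree`.
#' @param blood blood property list (density kg/m^3, specific_heat, conductivity).
#' @param nusselt Nusselt number of the wall-exchange closure (default 4).
#' @return a `thermal_system` with the sparse matrix, right-hand side and
#'   the bookkeeping needed by [solve_temperature()] and [energy_audit()].
#' @export
assemble_system <- function(props, bc = boundary_conditions(), demand = NULL,
                            tree = NULL, flows = NULL,
                            blood = thermal_properties()$blood, nusselt = 4) {
  grid <- props$grid
  mask <- props$mask
  shape <- grid$shape
  vox_lin <- which(mask)
  n_vox <- length(vox_lin)
  uidx <- array(0L, shape)
  uidx[vox_lin] <- seq_len(n_vox)
  dx_m <- grid$voxel_size * 1e-3
  vol_m3 <- prod(dx_m)
  c_b <- blood$specific_heat

  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add <- function(i, j, x) { ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x) }
  b <- numeric(n_vox)
  diag_acc <- numeric(n_vox)

  # conduction across interior faces, harmonic-mean conductivity
  k_arr <- props$conductivity
  for (ax in 1:3) {
    face_A <- prod(dx_m[-ax])
    d <- dx_m[ax]
    n <- shape[ax]
    idx_lo <- switch(ax, list(1:(n - 1), TRUE, TRUE), list(TRUE, 1:(n - 1), TRUE),
                     list(TRUE, TRUE, 1:(n - 1)))
    idx_hi <- switch(ax, list(2:n, TRUE, TRUE), list(TRUE, 2:n, TRUE),
                     list(TRUE, TRUE, 2:n))
    u_lo <- do.call(`[`, c(list(uidx), idx_lo))
    u_hi <- do.call(`[`, c(list(uidx), idx_hi))
    k_lo <- do.call(`[`, c(list(k_arr), idx_lo))
    k_hi <- do.call(`[`, c(list(k_arr), idx_hi))
    both <- u_lo > 0 & u_hi > 0
    kh <- 2 * k_lo[both] * k_hi[both] / (k_lo[both] + k_hi[both])
    g <- kh * face_A / d
    il <- u_lo[both]; ih <- u_hi[both]
    add(il, ih, g); add(ih, il, g)
    dacc <- tapply(c(g, g), c(il, ih), sum)
    diag_acc[as.integer(names(dacc))] <- diag_acc[as.integer(names(dacc))] +
      as.numeric(dacc)
  }

  # metabolic sources
  b <- b - props$metabolic[vox_lin] * vol_m3

  # Robin surface exchange on faces adjoining non-tissue or the domain edge
  robin_hA <- numeric(n_vox)
  if (bc$scalp_mode == "robin") {
    for (ax in 1:3) {
      face_A <- prod(dx_m[-ax])
      padded <- array(0L, shape + c(ax == 1, ax == 2, ax == 3) * 2)
      idx <- switch(ax, list(2:(shape[1] + 1), TRUE, TRUE),
                    list(TRUE, 2:(shape[2] + 1), TRUE),
                    list(TRUE, TRUE, 2:(shape[3] + 1)))
      padded <- do.call(`[<-`, c(list(padded), idx, list(uidx)))
      for (s in c(-1, 1)) {
        nb <- shift_array(padded, ax, s)
        nb <- do.call(`[`, c(list(nb), idx))
        ext <- uidx > 0 & nb == 0
        robin_hA[uidx[ext]] <- robin_hA[uidx[ext]] + bc$surface_coefficient * face_A
      }
    }
    diag_acc <- diag_acc + robin_hA
    b <- b - robin_hA * bc$ambient_temp
  }

  t_in <- inlet_temperature(bc)
  mode <- if (!is.null(tree)) "tree" else if (!is.null(demand)) "pennes" else "conduction"
  m_vox <- numeric(n_vox)   # capillary mass flow through each voxel, kg/s
  node_ids <- integer(0)

  if (mode == "pennes") {
    md <- demand$demand[vox_lin] * (blood$density / 1e3) / 1e3 / 60  # mL/min -> kg/s
    m_vox <- md
    diag_acc <- diag_acc + md * c_b
    b <- b - md * c_b * t_in
  }

  n_nodes <- 0L
  if (mode == "tree") {
    if (is.null(flows)) stop("tree mode requires a flow solution")
    nd <- tree$nodes
    node_ids <- nd$id
    n_nodes <- nrow(nd)
    nu <- function(id) n_vox + match(id, node_ids)  # unknown index of a node
    node_diag <- numeric(n_nodes)
    flow_kgs <- flows$flows$flow_mLmin[match(node_ids, flows$flows$id)] *
      (blood$density / 1e3) / 1e3 / 60
    pidx <- match(nd$parent, nd$id)
    len_m <- segment_lengths_mm(tree) * 1e-3
    cont <- containing_voxel(grid, as.matrix(nd[, c("x", "y", "z")]))
    cont_u <- ifelse(is.na(cont), 0L, uidx[pmax(cont, 1L)])

    # capillary coupling: voxel receives at its arterial terminal temperature,
    # returns at tissue temperature to its venous terminal
    va <- flows$voxel_assignment
    mv <- va$demand_mLmin * (blood$density / 1e3) / 1e3 / 60
    vu <- uidx[va$voxel]
    if (any(vu == 0)) stop("perfused voxel outside the property mask")
    m_vox[vu] <- m_vox[vu] + mv
    au <- nu(va$arterial_terminal)
    vnu <- nu(va$venous_terminal)
    # voxel rows: + m c (T_art_term - T_vox)
    add(vu, au, mv * c_b)
    dacc <- tapply(mv * c_b, vu, sum)
    diag_acc[as.integer(names(dacc))] <- diag_acc[as.integer(names(dacc))] +
      as.numeric(dacc)
    # venous terminal rows: + m c (T_vox - T_v)
    add(vnu, vu, mv * c_b)
    nacc <- tapply(mv * c_b, vnu - n_vox, sum)
    node_diag[as.integer(names(nacc))] <- node_diag[as.integer(names(nacc))] +
      as.numeric(nacc)

    # advection: arterial flows root->leaf (upstream = parent); venous flows
    # leaf->root (each node collects its children)
    for (i in seq_len(n_nodes)) {
      if (nd$side[i] == "arterial") {
        if (is.na(pidx[i])) next  # inlet handled as Dirichlet
        mcb <- flow_kgs[i] * c_b
        if (mcb > 0) {
          add(n_vox + i, n_vox + pidx[i], mcb)
          node_diag[i] <- node_diag[i] + mcb
        }
      } else if (!is.na(pidx[i])) {
        mcb <- flow_kgs[i] * c_b
        if (mcb > 0) {
          add(n_vox + pidx[i], n_vox + i, mcb)
          node_diag[pidx[i]] <- node_diag[pidx[i]] + mcb
        }
      }
    }

    # wall exchange with the containing voxel: h = Nu k_b / D over area
    # pi D L, so h A = Nu k_b pi L (the diameter cancels)
    hA <- ifelse(is.na(len_m), 0, nusselt * blood$conductivity * pi * len_m)
    ok <- cont_u > 0 & hA > 0
    add(n_vox + which(ok), cont_u[ok], hA[ok])
    node_diag[ok] <- node_diag[ok] + hA[ok]
    add(cont_u[ok], n_vox + which(ok), hA[ok])
    dacc <- tapply(hA[ok], cont_u[ok], sum)
    diag_acc[as.integer(names(dacc))] <- diag_acc[as.integer(names(dacc))] +
      as.numeric(dacc)

    diag_acc <- c(diag_acc, node_diag)
    b <- c(b, numeric(n_nodes))
    # Dirichlet inlet row: T_root = t_in replaces the root balance
    a_root <- which(nd$side == "arterial" & is.na(nd$parent))
    r <- n_vox + a_root
    keep <- ti != r
    ti <- ti[keep]; tj <- tj[keep]; tx <- tx[keep]
    diag_acc[r] <- 1
    b[r] <- -t_in
  }

  # residual form: sum_j g_ij T_j - diag_i T_i + (-b_i) = 0; stored as the
  # M-matrix  (diag_i on the diagonal, -g_ij off it) with rhs -b
  n_unknown <- n_vox + n_nodes
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(n_unknown)),
                            j = c(tj, seq_len(n_unknown)),
                            x = c(-tx, diag_acc), dims = c(n_unknown, n_unknown))
  zero_rows <- which(diag_acc == 0)
  if (length(zero_rows))
    stop(sprintf("%d disconnected unknown(s) (no conduction neighbour, no perfusion): first indices %s",
                 length(zero_rows), paste(utils::head(zero_rows, 5), collapse = ", ")))

  structure(list(A = A, b = -b, grid = grid, mask = mask, vox_lin = vox_lin,
                 node_ids = node_ids, n_vox = n_vox, mode = mode,
                 q_W = props$metabolic[vox_lin] * vol_m3, robin_hA = robin_hA,
                 ambient_temp = if (bc$scalp_mode == "robin") bc$ambient_temp else NA,
                 inlet_temp = t_in, m_vox_kgs = m_vox, c_b = c_b,
                 tree = tree, flows = flows, blood = blood),
            class = "thermal_system")
}

shift_array <- function(a, axis, s) {
  d <- dim(a)
  out <- array(0L, d)
  n <- d[axis]
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  idx_src <- switch(axis, list(src, TRUE, TRUE), list(TRUE, src, TRUE),
                    list(TRUE, TRUE, src))
  idx_dst <- switch(axis, list(dst, TRUE, TRUE), list(TRUE, dst, TRUE),
                    list(TRUE, TRUE, dst))
  do.call(`[<-`, c(list(out), idx_dst,
                   list(do.call(`[`, c(list(a), idx_src, list(drop = FALSE))))))
}

#' Solve the assembled thermal system
#'
#' Direct sparse factorization (the system sizes produced here stay well
#' below the point where an iterative method would pay off); the relative
#' residual is checked against `tolerance`.
#'
#' @param system a `thermal_system` from [assemble_system()].
#' @param tolerance maximum relative residual (default 1e-8).
#' @return a `temperature_field`: 3-D array `tissue` (NA outside the mask),
#'   data.frame `vessels` (id, side, temperature) and the final `residual`.
#' @export
solve_temperature <- function(system, tolerance = 1e-8) {
  x <- as.numeric(Matrix::solve(system$A, system$b))
  res <- sqrt(sum((as.numeric(system$A %*% x) - system$b)^2)) /
    max(sqrt(sum(system$b^2)), 1e-300)
  if (!is.finite(res) || res > tolerance)
    stop(sprintf("thermal solve did not reach tolerance: residual %.3e", res))
  tissue <- array(NA_real_, system$grid$shape)
  tissue[system$vox_lin] <- x[seq_len(system$n_vox)]
  vessels <- if (length(system$node_ids))
    data.frame(id = system$node_ids,
               side = system$tree$nodes$side[match(system$node_ids,
                                                   system$tree$nodes$id)],
               temperature = x[system$n_vox + seq_along(system$node_ids)])
  else data.frame(id = integer(0), side = character(0), temperature = numeric(0))
  structure(list(tissue = tissue, vessels = vessels, residual = res),
            class = "temperature_field")
}

#' Energy balance audit of a solved field
#'
#' Reports total metabolic power, net Robin boundary exchange, the enthalpy
#' exported by venous blood relative to the arterial inlet, and the relative
#' imbalance |in - out| / scale. The discretization is conservative, so the
#' imbalance is at the solver-residual level.
#'
#' @param field a `temperature_field`.
#' @param system the `thermal_system` it was solved from.
#' @return a list with `metabolic_W`, `boundary_W` (positive = into the
#'   brain), `venous_export_W`, `venous_out_C`, `arterial_in_C`,
#'   `relative_imbalance`.
#' @export
energy_audit <- function(field, system) {
  tvox <- field$tissue[system$vox_lin]
  q_met <- sum(system$q_W)
  q_robin <- if (!is.na(system$ambient_temp))
    sum(system$robin_hA * (system$ambient_temp - tvox)) else 0
  t_in <- system$inlet_temp
  if (system$mode == "tree") {
    nd <- system$tree$nodes
    v_root <- nd$id[nd$side == "venous" & is.na(nd$parent)]
    t_out <- field$vessels$temperature[match(v_root, field$vessels$id)]
    m_tot <- sum(system$flows$voxel_assignment$demand_mLmin) *
      (system$blood$density / 1e3) / 1e3 / 60
    export <- m_tot * system$c_b * (t_out - t_in)
  } else if (system$mode == "pennes") {
    export <- sum(system$m_vox_kgs * system$c_b * (tvox - t_in))
    t_out <- if (sum(system$m_vox_kgs) > 0)
      sum(system$m_vox_kgs * tvox) / sum(system$m_vox_kgs) else NA_real_
  } else {
    export <- 0; t_out <- NA_real_
  }
  scale <- max(abs(q_met), abs(export), abs(q_robin), 1e-12)
  list(metabolic_W = q_met, boundary_W = q_robin, venous_export_W = export,
       venous_out_C = t_out, arterial_in_C = t_in,
       relative_imbalance = abs(q_met + q_robin - export) / scale)
}

#' One-call biophysical simulation on a phantom
#'
#' Chains demand-map construction, vessel seeding, RRT densification,
#' Murray-law radii, flow distribution, system assembly and the thermal
#' solve.
#'
#' @param phantom a `tissue_phantom`.
#' @param bc a [boundary_conditions()].
#' @param table a [thermal_properties()].
#' @param cbf_gm,cbf_wm,tissue_density see [cbf_map_from_tpm()].
#' @param n_terminals,step_mm see [rrt_augment()].
#' @param terminal_diameter_um,murray_exponent see [assign_radii()].
#' @param mode "tree" for the discrete-vessel model, "pennes" for the
#'   perfusion-sink model without an explicit tree.
#' @param nusselt wall-exchange Nusselt number.
#' @param seed integer RNG seed for the vascular synthesis.
#' @return list with `field`, `audit`, `system`, `tree`, `flows`, `demand`.
#' @export
simulate_brain_temperature <- function(phantom, bc = boundary_conditions(),
                                       table = thermal_properties(),
                                       cbf_gm = 60, cbf_wm = 22,
                                       tissue_density = 1.045,
                                       n_terminals = 150, step_mm = NULL,
                                       terminal_diameter_um = 7,
                                       murray_exponent = 3,
                                       mode = c("tree", "pennes"),
                                       nusselt = 4, seed = 1L) {
  mode <- match.arg(mode)
  props <- voxel_properties(phantom, table)
  demand <- cbf_map_from_tpm(phantom, cbf_gm, cbf_wm, tissue_density)
  tree <- NULL; flows <- NULL
  if (mode == "tree") {
    tree <- make_vessel_seeds(phantom, seed = seed)
    tree <- rrt_augment(tree, demand, n_terminals = n_terminals,
                        step_mm = step_mm, seed = seed)
    tree <- assign_radii(tree, terminal_diameter_um, murray_exponent)
    flows <- solve_flows(tree, demand)
    system <- assemble_system(props, bc, demand = demand, tree = tree,
                              flows = flows, blood = table$blood,
                              nusselt = nusselt)
  } else {
    system <- assemble_system(props, bc, demand = demand, blood = table$blood)
  }
  field <- solve_temperature(system)
  audit <- energy_audit(field, system)
  list(field = field, audit = audit, system = system, tree = tree,
       flows = flows, demand = demand)
}
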