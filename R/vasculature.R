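#' Vessel tree container
#'
#' A directed forest of exactly two trees — one arterial (rooted at the
#' inlet) and one venous (rooted at the outlet). Nodes carry world positions
#' (mm) and radii (micrometres); segments are parent -> child pairs.
#'
#' @param nodes data.frame with columns `id` (integer, unique), `x`, `y`,
#'   `z` (mm), `radius_um` (> 0), `side` ("arterial"/"venous"), `parent`
#'   (id or NA for the root of each side).
#' @return a `vessel_tree`.
#' @export
vessel_tree <- function(nodes) {
  stopifnot(all(c("id", "x", "y", "z", "radius_um", "side", "parent") %in% names(nodes)))
  structure(list(nodes = nodes), class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<vessel_tree %d nodes (%d arterial, %d venous), %d terminals>\n",
              nrow(n), sum(n$side == "arterial"), sum(n$side == "venous"),
              length(tree_terminals(x, "arterial")) + length(tree_terminals(x, "venous"))))
  invisible(x)
}

#' Validate vessel-tree invariants
#'
#' Checks: one root per side, parents exist on the same side, no cycles,
#' radii > 0, segment lengths > 0, and (optionally) all node positions
#' inside a grid's world bounds.
#'
#' @param tree a `vessel_tree`.
#' @param grid optional [voxel_grid()] for the bounds check.
#' @return invisibly TRUE, or an error.
#' @export
validate_vessel_tree <- function(tree, grid = NULL) {
  n <- tree$nodes
  if (anyDuplicated(n$id)) stop("duplicate node ids")
  for (s in c("arterial", "venous")) {
    ns <- n[n$side == s, ]
    if (sum(is.na(ns$parent)) != 1L) stop("need exactly one ", s, " root")
    if (!all(ns$parent[!is.na(ns$parent)] %in% ns$id))
      stop("parent missing or crosses sides on the ", s, " tree")
  }
  if (any(n$radius_um <= 0)) stop("radii must be > 0")
  pidx <- match(n$parent, n$id)
  seg <- which(!is.na(pidx))
  len <- sqrt((n$x[seg] - n$x[pidx[seg]])^2 + (n$y[seg] - n$y[pidx[seg]])^2 +
              (n$z[seg] - n$z[pidx[seg]])^2)
  if (any(len <= 0)) stop("zero-length segment")
  # cycle check: following parents must terminate
  for (i in seq_len(nrow(n))) {
    j <- i; steps <- 0L
    while (!is.na(pidx[j])) {
      j <- pidx[j]; steps <- steps + 1L
      if (steps > nrow(n)) stop("cycle detected in vessel tree")
    }
  }
  if (!is.null(grid)) {
    v <- world_to_voxel(grid, as.matrix(n[, c("x", "y", "z")]))
    if (any(v < -0.5) || any(sweep(v, 2, grid$shape - 0.5, `>=`)))
      stop("node position outside the grid bounds")
  }
  invisible(TRUE)
}

tree_terminals <- function(tree, side) {
  n <- tree$nodes[tree$nodes$side == side, ]
  setdiff(n$id, n$parent[!is.na(n$parent)])
}

segment_lengths_mm <- function(tree) {
  n <- tree$nodes
  pidx <- match(n$parent, n$id)
  len <- rep(NA_real_, nrow(n))
  seg <- which(!is.na(pidx))
  len[seg] <- sqrt((n$x[seg] - n$x[pidx[seg]])^2 + (n$y[seg] - n$y[pidx[seg]])^2 +
                   (n$z[seg] - n$z[pidx[seg]])^2)
  len
}

#' Write / read a vessel tree in SWC format
#'
#' Plain-text SWC: one row per node, columns id, type, x, y, z, radius,
#' parent (-1 for roots). Type code 2 marks arterial and 3 venous nodes
#' (a documented custom mapping); coordinates are mm and the radius column
#' is in micrometres.
#'
#' @param tree a `vessel_tree`.
#' @param path output file.
#' @return `write_swc` the path invisibly; `read_swc` a `vessel_tree`.
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes
  type <- ifelse(n$side == "arterial", 2L, 3L)
  parent <- ifelse(is.na(n$parent), -1L, n$parent)
  lines <- c("# SWC vessel tree: type 2 = arterial, 3 = venous; xyz mm, radius um",
             sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                     n$id, type, n$x, n$y, n$z, n$radius_um, parent))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius_um", "parent"))
  tab$side <- ifelse(tab$type == 2L, "arterial", "venous")
  tab$parent <- ifelse(tab$parent < 0, NA_integer_, tab$parent)
  vessel_tree(tab[, c("id", "x", "y", "z", "radius_um", "side", "parent")])
}

#' Perfusion demand map from tissue probability maps
#'
#' Per-voxel blood demand (mL/min) from a priori grey- and white-matter
#' perfusion rates:
#' demand = (tpm_gm * cbf_gm + tpm_wm * cbf_wm) / 100 * density * V_mL.
#'
#' @param phantom a `tissue_phantom`.
#' @param cbf_gm,cbf_wm perfusion, mL per 100 g per min (defaults 60, 22).
#' @param tissue_density tissue density, g/mL (default 1.045).
#' @return a `perfusion_demand`: list(grid, demand) with demand in mL/min
#'   per voxel, zero on pure CSF and background.
#' @export
cbf_map_from_tpm <- function(phantom, cbf_gm = 60, cbf_wm = 22,
                             tissue_density = 1.045) {
  if (cbf_gm <= 0 || cbf_wm <= 0) stop("CBF values must be > 0")
  v_ml <- voxel_volume(phantom$grid, "mL")
  demand <- (phantom$tpm_gm * cbf_gm + phantom$tpm_wm * cbf_wm) / 100 *
    tissue_density * v_ml
  structure(list(grid = phantom$grid, demand = demand),
            class = "perfusion_demand")
}

#' Densify a vessel tree with a rapidly exploring random tree
#'
#' Iteratively samples a voxel with probability proportional to its unmet
#' perfusion demand and extends the tree from the nearest node of each side
#' toward that voxel centre in steps of at most `step_mm`; when the target
#' is reached the new node becomes a terminal and claims the voxel's demand.
#' Growth is denser where demand is higher. Deterministic given the seed.
#'
#' @param tree a `vessel_tree` of coarse seed branches.
#' @param demand a `perfusion_demand`.
#' @param n_terminals new terminals to add per side.
#' @param step_mm maximum extension step (default 2 x mean voxel size).
#' @param seed integer RNG seed.
#' @return the augmented `vessel_tree`; attribute `shortfall` reports
#'   per-side terminals not placed if demand was exhausted early.
#' @export
rrt_augment <- function(tree, demand, n_terminals = 200, step_mm = NULL,
                        seed = 1L) {
  if (n_terminals < 1) stop("`n_terminals` must be >= 1")
  validate_vessel_tree(tree)
  if (is.null(step_mm)) step_mm <- 2 * mean(demand$grid$voxel_size)
  set.seed(as.integer(seed))
  centers <- grid_world_coords(demand$grid)
  dem0 <- as.numeric(demand$demand)
  shortfall <- c(arterial = 0L, venous = 0L)
  nodes <- tree$nodes
  next_id <- max(nodes$id) + 1L

  for (side in c("arterial", "venous")) {
    rem <- dem0
    sel <- nodes$side == side
    pos <- as.matrix(nodes[sel, c("x", "y", "z")])
    ids <- nodes$id[sel]
    new_pos <- matrix(0, 0, 3); new_par <- integer(0); new_ids <- integer(0)
    added <- 0L
    while (added < n_terminals) {
      tot <- sum(rem)
      if (tot <= 0) { shortfall[side] <- n_terminals - added; break }
      vx <- sample.int(length(rem), 1L, prob = rem)
      target <- centers[vx, ]
      # walk from the nearest node toward the target in <= step_mm hops
      repeat {
        d2 <- (pos[, 1] - target[1])^2 + (pos[, 2] - target[2])^2 +
              (pos[, 3] - target[3])^2
        j <- which.min(d2)
        gap <- sqrt(d2[j])
        reach <- gap <= step_mm
        newp <- if (reach) target else
          pos[j, ] + (target - pos[j, ]) * (step_mm / gap)
        id <- next_id; next_id <- next_id + 1L
        pos <- rbind(pos, newp); ids <- c(ids, id)
        new_pos <- rbind(new_pos, newp); new_ids <- c(new_ids, id)
        new_par <- c(new_par, ids[j])
        if (reach) { rem[vx] <- 0; added <- added + 1L; break }
      }
    }
    if (length(new_ids))
      nodes <- rbind(nodes,
                     data.frame(id = new_ids, x = new_pos[, 1], y = new_pos[, 2],
                                z = new_pos[, 3], radius_um = 3.5, side = side,
                                parent = new_par, stringsAsFactors = FALSE))
  }
  if (any(shortfall > 0))
    warning(sprintf("demand exhausted early: %d arterial / %d venous terminals not placed",
                    shortfall["arterial"], shortfall["venous"]))
  out <- vessel_tree(nodes)
  attr(out, "shortfall") <- shortfall
  out
}

#' Assign vessel radii by Murray's law
#'
#' Terminals get the capillary radius (`terminal_diameter_um / 2`); every
#' parent then satisfies r_parent^gamma = sum of r_child^gamma, applied
#' leaf-to-root, so root radii are fully determined. Along an unbranched
#' chain the radius is constant.
#'
#' @param tree a `vessel_tree`.
#' @param terminal_diameter_um capillary diameter (default 7).
#' @param murray_exponent branching exponent gamma (default 3).
#' @return the `vessel_tree` with updated `radius_um`.
#' @export
assign_radii <- function(tree, terminal_diameter_um = 7, murray_exponent = 3) {
  n <- tree$nodes
  pidx <- match(n$parent, n$id)
  kids <- split(seq_len(nrow(n)), pidx)
  rg <- rep(0, nrow(n))  # r^gamma accumulated from leaves
  term <- !(seq_len(nrow(n)) %in% pidx[!is.na(pidx)])
  rg[term] <- (terminal_diameter_um / 2)^murray_exponent
  # process in order of decreasing depth
  depth <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    j <- i
    while (!is.na(pidx[j])) { j <- pidx[j]; depth[i] <- depth[i] + 1L }
  }
  for (i in order(depth, decreasing = TRUE)) {
    ch <- kids[[as.character(i)]]
    if (!is.null(ch)) rg[i] <- sum(rg[ch])
  }
  n$radius_um <- rg^(1 / murray_exponent)
  vessel_tree(n)
}

#' Distribute perfusion demand through the tree with exact mass conservation
#'
#' Every demand voxel is assigned to its nearest arterial terminal and its
#' nearest venous terminal; terminal flows are the summed assigned demand,
#' internal segment flows are the summed downstream terminal flows, and the
#' inlet/outlet flows equal the total demand on each side — conservation is
#' exact by construction and asserted to 1e-12 relative.
#'
#' @param tree a `vessel_tree` with radii assigned.
#' @param demand a `perfusion_demand`.
#' @return a `flow_solution`: `flows` (data.frame id, side, flow_mLmin =
#'   flow through the segment entering the node; total at each root),
#'   `voxel_assignment` (data.frame voxel, demand_mLmin, arterial_terminal,
#'   venous_terminal), `total_mLmin`.
#' @export
solve_flows <- function(tree, demand) {
  n <- tree$nodes
  dem <- as.numeric(demand$demand)
  vox <- which(dem > 0)
  if (!length(vox)) {
    warning("zero total demand: all flows are zero")
    return(structure(list(flows = data.frame(id = n$id, side = n$side,
                                             flow_mLmin = 0),
                          voxel_assignment = data.frame(voxel = integer(0),
                                                        demand_mLmin = numeric(0),
                                                        arterial_terminal = integer(0),
                                                        venous_terminal = integer(0)),
                          total_mLmin = 0), class = "flow_solution"))
  }
  centers <- grid_world_coords(demand$grid)[vox, , drop = FALSE]
  assign_side <- function(side) {
    tids <- tree_terminals(tree, side)
    tpos <- as.matrix(n[match(tids, n$id), c("x", "y", "z")])
    nearest <- apply_nearest(centers, tpos)
    tids[nearest]
  }
  a_term <- assign_side("arterial")
  v_term <- assign_side("venous")

  flow <- numeric(nrow(n))
  add_terminal_flows <- function(term_ids, flow) {
    agg <- tapply(dem[vox], term_ids, sum)
    flow[match(as.integer(names(agg)), n$id)] <-
      flow[match(as.integer(names(agg)), n$id)] + as.numeric(agg)
    flow
  }
  flow <- add_terminal_flows(a_term, flow)
  flow <- add_terminal_flows(v_term, flow)
  # push terminal flows up to the roots (deepest first)
  pidx <- match(n$parent, n$id)
  depth <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    j <- i
    while (!is.na(pidx[j])) { j <- pidx[j]; depth[i] <- depth[i] + 1L }
  }
  for (i in order(depth, decreasing = TRUE))
    if (!is.na(pidx[i])) flow[pidx[i]] <- flow[pidx[i]] + flow[i]

  total <- sum(dem[vox])
  for (s in c("arterial", "venous")) {
    root <- n$id[is.na(n$parent) & n$side == s]
    stopifnot(abs(flow[match(root, n$id)] - total) <= 1e-12 * total)
  }
  structure(list(flows = data.frame(id = n$id, side = n$side, flow_mLmin = flow),
                 voxel_assignment = data.frame(voxel = vox,
                                               demand_mLmin = dem[vox],
                                               arterial_terminal = a_term,
                                               venous_terminal = v_term),
                 total_mLmin = total),
            class = "flow_solution")
}

# row-wise nearest reference index, chunked to bound memory
apply_nearest <- function(pts, ref) {
  out <- integer(nrow(pts))
  step <- 2048L
  r2 <- rowSums(ref^2)
  for (s in seq(1L, nrow(pts), by = step)) {
    e <- min(s + step - 1L, nrow(pts))
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), r2, `+`) - 2 * block %*% t(ref)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}
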