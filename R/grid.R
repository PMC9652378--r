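#' Voxel grid geometry
#'
#' A `voxel_grid` describes a regular 3-D sampling lattice: the array shape,
#' the physical voxel size in mm, and a 4x4 affine mapping 0-based voxel
#' indices (i, j, k) to world coordinates in mm. By default the grid is
#' centred on the world origin.
#'
#' @param shape integer length-3; array dimensions, each >= 8.
#' @param voxel_size numeric length 1 or 3; voxel edge lengths in mm, > 0.
#' @param origin optional world position (mm) of voxel (0,0,0); default centres
#'   the volume on the origin.
#' @return An object of class `voxel_grid` with fields `shape`, `voxel_size`
#'   and `affine`.
#' @export
voxel_grid <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(round(shape))
  if (length(shape) != 3L || any(shape < 8L))
    stop("`shape` must be three integers, each >= 8")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive")
  if (is.null(origin)) origin <- -(shape - 1) * voxel_size / 2
  affine <- diag(4)
  affine[cbind(1:3, 1:3)] <- voxel_size
  affine[1:3, 4] <- origin
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s, voxel %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Voxel-centre world coordinates
#'
#' @param grid a `voxel_grid`.
#' @return An N x 3 matrix of world coordinates (mm) for every voxel centre,
#'   in column-major array order.
#' @export
grid_world_coords <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape) - 1L
  voxel_to_world(grid, idx)
}

#' Map 0-based voxel indices to world mm
#' @param grid a `voxel_grid`.
#' @param ijk N x 3 matrix of 0-based voxel indices (may be fractional).
#' @return N x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(grid$affine[1:3, 1:3] %*% t(ijk)) +
    matrix(grid$affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
}

#' Map world mm to (fractional) 0-based voxel indices
#' @param grid a `voxel_grid`.
#' @param xyz N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(xyz)) +
    matrix(inv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
}

#' Linear array index of the voxel containing each world point
#'
#' Points outside the grid return NA.
#' @param grid a `voxel_grid`.
#' @param xyz N x 3 matrix of world coordinates (mm).
#' @return integer vector of 1-based linear indices into the voxel array.
#' @export
containing_voxel <- function(grid, xyz) {
  ijk <- round(world_to_voxel(grid, xyz))
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
        ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
        ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
  out <- rep(NA_integer_, nrow(ijk))
  out[ok] <- 1L + ijk[ok, 1] + grid$shape[1] * (ijk[ok, 2] + grid$shape[2] * ijk[ok, 3])
  out
}

#' Volume of one voxel
#' @param grid a `voxel_grid`.
#' @param units `"mm3"`, `"mL"` or `"m3"`.
#' @return scalar voxel volume.
#' @export
voxel_volume <- function(grid, units = c("mm3", "mL", "m3")) {
  units <- match.arg(units)
  v <- prod(grid$voxel_size)
  switch(units, mm3 = v, mL = v / 1e3, m3 = v / 1e9)
}
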