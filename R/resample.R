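#' Degree-4 B-spline resampling of a temperature map
#'
#' Resamples map values onto a target grid through an affine transform using
#' quartic (degree-4) B-spline interpolation: the source volume is converted
#' to B-spline coefficients with the standard recursive prefilter (mirror
#' boundaries), then evaluated at the transformed target voxel centres.
#' The QC mask is resampled with nearest-neighbour lookup; target voxels
#' that fall outside the source volume, or on masked-out source voxels, are
#' undefined. Undefined source voxels are filled by nearest-defined values
#' before prefiltering so the spline is not dragged toward zero at the mask
#' edge.
#'
#' @param map a `temperature_map` (see [qc_filter()]).
#' @param target a [voxel_grid()] to resample onto.
#' @param transform 4x4 affine mapping source world coordinates (mm) to
#'   target world coordinates; must be invertible. Default identity.
#' @return a `temperature_map` on `target`.
#' @export
resample_map <- function(map, target, transform = diag(4)) {
  if (!inherits(map, "temperature_map")) stop("`map` must be a temperature_map")
  if (abs(det(transform)) < 1e-12) stop("`transform` is singular")
  src <- map$grid
  tgt_world <- grid_world_coords(target)
  src_world <- t(solve(transform) %*% rbind(t(tgt_world), 1))[, 1:3, drop = FALSE]
  coords <- world_to_voxel(src, src_world)

  inside <- coords[, 1] >= 0 & coords[, 1] <= src$shape[1] - 1 &
            coords[, 2] >= 0 & coords[, 2] <= src$shape[2] - 1 &
            coords[, 3] >= 0 & coords[, 3] <= src$shape[3] - 1

  filled <- fill_nearest(map$values, map$qc_mask)
  coef <- bspline_prefilter(filled)
  vals <- rep(NA_real_, nrow(coords))
  vals[inside] <- bspline_eval(coef, coords[inside, , drop = FALSE])

  nn <- round(coords)
  nn_ok <- inside
  mask_out <- rep(FALSE, nrow(coords))
  sel <- which(nn_ok)
  lin <- 1L + nn[sel, 1] + src$shape[1] * (nn[sel, 2] + src$shape[2] * nn[sel, 3])
  mask_out[sel] <- map$qc_mask[lin]
  vals[!mask_out] <- NA_real_

  new_temperature_map(target, array(vals, target$shape),
                      array(mask_out, target$shape), map$qc_report)
}

# fill undefined voxels with nearest defined values by repeated face-neighbour
# averaging; returns a fully defined array (0 if nothing defined)
fill_nearest <- function(x, mask) {
  out <- x
  out[!mask] <- NA_real_
  if (!any(mask)) return(array(0, dim(x)))
  g <- c(0.25, 0.5, 0.25)
  for (it in seq_len(sum(dim(x)))) {
    nas <- is.na(out)
    if (!any(nas)) break
    m <- !nas
    tmp <- out; tmp[nas] <- 0
    num <- separable_conv3(tmp, g)
    den <- separable_conv3(array(as.numeric(m), dim(x)), g)
    upd <- nas & den > 0
    out[upd] <- num[upd] / den[upd]
  }
  out[is.na(out)] <- 0
  out
}

# quartic B-spline kernel, support |x| <= 2.5, by divided differences
bspline4_kernel <- function(x) {
  out <- 0
  for (k in 0:5) out <- out + (-1)^k * choose(5, k) * pmax(0, x + 2.5 - k)^4
  out / 24
}

# recursive direct B-spline transform (degree 4), mirror boundary conditions
bspline_prefilter <- function(x) {
  poles <- c(sqrt(664 - sqrt(438976)) + sqrt(304) - 19,
             sqrt(664 + sqrt(438976)) - sqrt(304) - 19)
  for (axis in 1:3) x <- prefilter_axis(x, axis, poles)
  x
}

prefilter_axis <- function(x, axis, poles) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(x, perm)
  n <- d[axis]
  dim(m) <- c(n, prod(d[-axis]))
  for (z in poles) {
    m <- m * (1 - z) * (1 - 1 / z)
    # causal pass
    h <- ceiling(log(1e-14) / log(abs(z)))
    if (h < n) {
      zs <- z^(0:(h - 1))
      c0 <- drop(zs %*% m[1:h, , drop = FALSE])
    } else {
      zn <- z^(n - 1)
      k <- 1:(n - 2)
      w <- c(1, z^k + z^(2 * n - 2 - k), zn)
      c0 <- drop(w %*% m) / (1 - z^(2 * n - 2))
    }
    cp <- m
    cp[1, ] <- c0
    for (k in 2:n) cp[k, ] <- m[k, ] + z * cp[k - 1, ]
    # anticausal pass
    cm <- cp
    cm[n, ] <- (z / (z^2 - 1)) * (cp[n, ] + z * cp[n - 1, ])
    for (k in (n - 1):1) cm[k, ] <- z * (cm[k + 1, ] - cp[k, ])
    m <- cm
  }
  dim(m) <- c(n, d[-axis])
  aperm(m, order(perm))
}

# evaluate quartic B-spline series at fractional 0-based voxel coordinates
bspline_eval <- function(coef, coords) {
  d <- dim(coef)
  base <- round(coords)
  frac <- coords - base
  w <- lapply(1:3, function(a)
    vapply(-2:2, function(t) bspline4_kernel(frac[, a] - t),
           numeric(nrow(coords))))
  if (nrow(coords) == 1L) w <- lapply(w, function(v) matrix(v, nrow = 1L))
  mirror <- function(i, n) {
    if (n == 1) return(rep(0L, length(i)))
    p <- abs(i) %% (2L * n - 2L)
    ifelse(p > n - 1L, 2L * n - 2L - p, p)
  }
  out <- numeric(nrow(coords))
  for (tx in 1:5) {
    ix <- mirror(base[, 1] + tx - 3L, d[1])
    for (ty in 1:5) {
      iy <- mirror(base[, 2] + ty - 3L, d[2])
      wxy <- w[[1]][, tx] * w[[2]][, ty]
      for (tz in 1:5) {
        iz <- mirror(base[, 3] + tz - 3L, d[3])
        lin <- 1L + ix + d[1] * (iy + d[2] * iz)
        out <- out + wxy * w[[3]][, tz] * coef[lin]
      }
    }
  }
  out
}
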