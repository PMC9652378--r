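#' Fraction of voxels agreeing within a temperature threshold
#'
#' Percentage of jointly defined voxels whose absolute model-measurement
#' difference is at most `threshold` (inclusive; default 0.8 degrees C, the
#' published uncertainty of absolute MR temperature measurements).
#'
#' @param t_model,t_mr `temperature_map`s or 3-D arrays on the same grid.
#' @param threshold agreement threshold, degrees C.
#' @return percentage in [0, 100].
#' @export
within_threshold <- function(t_model, t_mr, threshold = 0.8) {
  a <- map_values(t_model); b <- map_values(t_mr)
  if (!identical(dim(a), dim(b))) stop("maps must share a grid")
  joint <- !is.na(a) & !is.na(b)
  if (!any(joint)) stop("empty joint QC mask: no jointly defined voxels")
  100 * mean(abs(a[joint] - b[joint]) <= threshold)
}

map_values <- function(x) {
  if (inherits(x, "temperature_map")) {
    v <- x$values; v[!x$qc_mask] <- NA_real_; v
  } else if (inherits(x, "temperature_field")) x$tissue
  else x
}

#' Per-region temperature statistics
#'
#' Mean and SD over QC-passing voxels per ROI. Regions whose bounding-box
#' extent along any axis is smaller than `min_dim_mm` (default the original
#' EPSI voxel size, 4.4 x 4.4 x 5.6 mm) are flagged excluded; regions with
#' no QC-passing voxels are flagged missing rather than silently dropped.
#'
#' @param map a `temperature_map` or 3-D array aligned with the phantom grid.
#' @param phantom a `tissue_phantom` supplying labels and roi_table.
#' @param min_dim_mm length-3 minimum region extent per axis, mm.
#' @return data.frame: id, name, hemisphere, class, n_voxels, mean, sd,
#'   extent_x/y/z_mm, excluded, missing.
#' @export
regional_stats <- function(map, phantom, min_dim_mm = c(4.4, 4.4, 5.6)) {
  vals <- map_values(map)
  if (!identical(dim(vals), dim(phantom$labels)))
    stop("map and phantom labels are on different grids")
  rt <- phantom$roi_table
  vs <- phantom$grid$voxel_size
  out <- rt
  out$n_voxels <- 0L; out$mean <- NA_real_; out$sd <- NA_real_
  out$extent_x_mm <- 0; out$extent_y_mm <- 0; out$extent_z_mm <- 0
  out$excluded <- FALSE; out$missing <- FALSE
  for (r in seq_len(nrow(rt))) {
    sel <- which(phantom$labels == rt$id[r])
    if (!length(sel)) {  # region absent from this parcellation
      out$missing[r] <- TRUE
      out$excluded[r] <- TRUE
      next
    }
    ijk <- arrayInd(sel, dim(phantom$labels))
    ext <- (apply(ijk, 2, max) - apply(ijk, 2, min) + 1) * vs
    out$extent_x_mm[r] <- ext[1]; out$extent_y_mm[r] <- ext[2]
    out$extent_z_mm[r] <- ext[3]
    out$excluded[r] <- any(ext < min_dim_mm)
    v <- vals[sel]
    v <- v[!is.na(v)]
    out$n_voxels[r] <- length(v)
    if (!length(v)) { out$missing[r] <- TRUE; next }
    out$mean[r] <- mean(v)
    out$sd[r] <- if (length(v) > 1) stats::sd(v) else 0
  }
  out
}

#' Subjects x regions temperature matrix
#'
#' @param values numeric matrix, one row per subject, one column per ROI
#'   (columns named by ROI id or name).
#' @param roi_meta data.frame with id, name, hemisphere, class matching the
#'   columns (default [phantom_roi_table()]).
#' @return a `regional_matrix`.
#' @export
regional_matrix <- function(values, roi_meta = phantom_roi_table()) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(roi_meta))
    stop("column count must match the ROI metadata")
  if (any(!is.finite(values)))
    stop("regional matrix has undefined cells for included ROIs")
  structure(list(values = values, roi = roi_meta,
                 n_subjects = nrow(values), n_rois = ncol(values)),
            class = "regional_matrix")
}

#' @export
print.regional_matrix <- function(x, ...) {
  cat(sprintf("<regional_matrix %d subjects x %d ROIs = %d cells>\n",
              x$n_subjects, x$n_rois, length(x$values)))
  invisible(x)
}

#' Z-standardize a regional temperature matrix
#'
#' Pooled standardization (default) centres and scales all subject x region
#' cells of one method jointly, so the output has mean 0 and SD 1 over all
#' cells; `by = "subject"` standardizes each subject's row separately.
#'
#' @param rm a [regional_matrix()].
#' @param by "pooled" or "subject".
#' @return matrix of Z-scores with the input dimensions.
#' @export
zscore_regions <- function(rm, by = c("pooled", "subject")) {
  by <- match.arg(by)
  v <- rm$values
  if (by == "pooled") {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero variance: cannot Z-standardize")
    (v - mean(v)) / s
  } else {
    t(apply(v, 1, function(row) {
      s <- stats::sd(row)
      if (!is.finite(s) || s == 0) stop("zero variance in a subject row")
      (row - mean(row)) / s
    }))
  }
}

#' Bland-Altman agreement between two Z-score (or value) sets
#'
#' Differences d = x - y; bias = mean(d); limits of agreement are
#' bias +/- `loa_multiplier` * SD(d) (1.96 by convention). Reports the
#' fraction of pairs inside the limits.
#'
#' @param x,y matched numeric vectors/matrices (>= 3 pairs).
#' @param loa_multiplier half-width of the limits in SD units.
#' @return list: bias, sd, loa_low, loa_high, fraction_within_loa_pct, n,
#'   and the paired data (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Bland-Altman needs at least 3 matched pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - loa_multiplier * s
  hi <- bias + loa_multiplier * s
  list(bias = bias, sd = s, loa_low = lo, loa_high = hi,
       fraction_within_loa_pct = 100 * mean(d >= lo & d <= hi),
       n = length(d), mean = (x + y) / 2, diff = d)
}

#' Hemispheric and cortical/subcortical temperature contrasts
#'
#' Mean over left-hemisphere ROIs minus right, and mean over subcortical
#' ROIs minus cortical, averaged across subjects.
#'
#' @param rm a [regional_matrix()].
#' @return list: hemisphere_L_minus_R, subcortical_minus_cortical (degrees C).
#' @export
regional_contrasts <- function(rm) {
  left <- rm$roi$hemisphere == "L"
  sub <- rm$roi$class == "subcortical"
  per_subj_h <- rowMeans(rm$values[, left, drop = FALSE]) -
    rowMeans(rm$values[, !left, drop = FALSE])
  per_subj_c <- rowMeans(rm$values[, sub, drop = FALSE]) -
    rowMeans(rm$values[, !sub, drop = FALSE])
  list(hemisphere_L_minus_R = mean(per_subj_h),
       subcortical_minus_cortical = mean(per_subj_c))
}
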