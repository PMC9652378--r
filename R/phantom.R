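#' Synthetic brain tissue phantom
#'
#' Builds a schematic, mirror-symmetric brain phantom on a regular voxel
#' grid: an outer CSF rim, a cortical grey-matter shell split into 10
#' cortical regions (left/right frontal, parietal, temporal, occipital
#' lobes and insula), a white-matter interior carrying 12 subcortical
#' regions (left/right cerebral WM, cerebellar WM, cerebellar cortex,
#' thalamus, putamen, pallidum), and a central CSF ventricle. Each voxel
#' carries GM/WM/CSF tissue probability fractions summing to at most 1.
#'
#' The geometry is deliberately schematic (concentric ellipsoidal shells and
#' nuclei spheres): downstream analyses only require 22 labelled regions
#' tagged by hemisphere and cortical/subcortical class, each large enough to
#' survive the regional minimum-extent exclusion rule.
#'
#' @param shape integer length-3 array dimensions, each >= 16.
#' @param voxel_size voxel edge length(s) in mm.
#' @param seed integer; reserved for optional stochastic texture
#'   (`texture_sd > 0`). The default phantom is purely geometric, so the same
#'   arguments always reproduce the same volume.
#' @param texture_sd optional SD of a smooth multiplicative texture applied
#'   to the GM/WM fractions (0 = none, the default; texture breaks exact
#'   mirror symmetry).
#' @return A `tissue_phantom`: list with `grid` (a [voxel_grid()]), 3-D
#'   arrays `tpm_gm`, `tpm_wm`, `tpm_csf`, an integer label array `labels`
#'   (0 = unlabelled), and `roi_table` (id, name, hemisphere, class).
#' @export
make_phantom <- function(shape = c(32L, 32L, 32L), voxel_size = 4, seed = 1L,
                         texture_sd = 0) {
  shape <- as.integer(round(shape))
  if (length(shape) != 3L || any(shape < 16L))
    stop("`shape` must be three integers >= 16: smaller grids cannot host all 22 regions")
  grid <- voxel_grid(shape, voxel_size)

  cen <- (shape - 1) / 2
  half <- (shape - 1) / 2
  ux <- (seq_len(shape[1]) - 1 - cen[1]) / half[1]
  uy <- (seq_len(shape[2]) - 1 - cen[2]) / half[2]
  uz <- (seq_len(shape[3]) - 1 - cen[3]) / half[3]
  UX <- array(ux, shape)
  UY <- array(rep(uy, each = shape[1]), shape)
  UZ <- array(rep(uz, each = shape[1] * shape[2]), shape)
  RHO <- sqrt(UX^2 + UY^2 + UZ^2)

  roi_table <- phantom_roi_table()
  labels <- array(0L, shape)
  tpm_gm <- array(0, shape); tpm_wm <- array(0, shape); tpm_csf <- array(0, shape)

  outer_r <- 0.95; rim_r <- 0.85; insula_r <- 0.62; interior_r <- 0.55
  vent_r <- 0.10

  csf_zone <- (RHO <= outer_r & RHO > rim_r) | RHO <= vent_r
  cortex_zone <- RHO <= rim_r & RHO > interior_r
  interior_zone <- RHO <= interior_r & RHO > vent_r

  left <- UX < 0
  id_of <- function(name, hemi) roi_table$id[roi_table$name == name & roi_table$hemisphere == hemi]
  put <- function(mask, name) {
    labels[mask & left] <<- id_of(name, "L")
    labels[mask & !left] <<- id_of(name, "R")
  }

  # cortical shell: insula innermost sub-shell, then four quadrant lobes
  put(cortex_zone & RHO <= insula_r, "insula")
  lobes <- cortex_zone & RHO > insula_r
  put(lobes & UY >= 0 & UZ >= 0, "frontal")
  put(lobes & UY < 0 & UZ >= 0, "parietal")
  put(lobes & UY >= 0 & UZ < 0, "temporal")
  put(lobes & UY < 0 & UZ < 0, "occipital")

  # interior: cerebral WM background, cerebellum wedge, deep grey nuclei
  put(interior_zone, "cerebral-wm")
  cereb <- interior_zone & UZ < -0.20 & UY < -0.10
  put(cereb & RHO > 0.40, "cerebellar-cortex")
  put(cereb & RHO <= 0.40, "cerebellar-wm")
  nucleus <- function(cx, cy, cz, r) {
    (sqrt((abs(UX) - cx)^2 + (UY - cy)^2 + (UZ - cz)^2) <= r) & interior_zone & !cereb
  }
  put(nucleus(0.18, -0.05, 0.03, 0.13), "thalamus")
  put(nucleus(0.40, 0.05, -0.05, 0.11), "putamen")
  put(nucleus(0.24, 0.18, 0.08, 0.10), "pallidum")

  missing_rois <- setdiff(roi_table$id, unique(as.integer(labels)))
  if (length(missing_rois))
    stop(sprintf("shape %s too small to host all 22 regions (empty: %s); use a larger grid",
                 paste(shape, collapse = "x"),
                 paste(roi_table$name[roi_table$id %in% missing_rois], collapse = ", ")))

  cls <- roi_table$class[match(as.integer(labels), roi_table$id)]
  gray_shell <- !is.na(cls) & cls == "cortical"
  nuclei <- labels %in% roi_table$id[roi_table$name %in% c("thalamus", "putamen", "pallidum")]
  cereb_ctx <- labels %in% roi_table$id[roi_table$name == "cerebellar-cortex"]
  wm_zone <- !is.na(cls) & cls == "subcortical" & !nuclei & !cereb_ctx

  tpm_gm[gray_shell] <- 0.85; tpm_wm[gray_shell] <- 0.10; tpm_csf[gray_shell] <- 0.05
  tpm_gm[cereb_ctx] <- 0.80; tpm_wm[cereb_ctx] <- 0.15; tpm_csf[cereb_ctx] <- 0.05
  tpm_gm[wm_zone] <- 0.10; tpm_wm[wm_zone] <- 0.85; tpm_csf[wm_zone] <- 0.05
  tpm_gm[nuclei] <- 0.60; tpm_wm[nuclei] <- 0.35; tpm_csf[nuclei] <- 0.05
  tpm_csf[csf_zone] <- 1

  if (texture_sd > 0) {
    set.seed(as.integer(seed))
    tex <- gaussian_smooth(array(stats::rnorm(prod(shape)), shape), sigma = 1)
    tex <- 1 + texture_sd * tex / stats::sd(tex)
    sel <- tpm_gm + tpm_wm > 0
    tot <- tpm_gm + tpm_wm + tpm_csf
    tpm_gm[sel] <- pmin(pmax(tpm_gm[sel] * tex[sel], 0.01), 0.95)
    tpm_wm[sel] <- pmax(tot[sel] - tpm_csf[sel] - tpm_gm[sel], 0.01)
  }

  structure(list(grid = grid, tpm_gm = tpm_gm, tpm_wm = tpm_wm,
                 tpm_csf = tpm_csf, labels = labels, roi_table = roi_table),
            class = "tissue_phantom")
}

#' Default 22-region parcellation table
#'
#' Ten cortical regions (frontal, parietal, temporal, occipital lobes and
#' insula, per hemisphere) and twelve subcortical regions (cerebral WM,
#' cerebellar WM, cerebellar cortex, thalamus, putamen, pallidum, per
#' hemisphere).
#' @return data.frame with columns id, name, hemisphere ("L"/"R"), class
#'   ("cortical"/"subcortical").
#' @export
phantom_roi_table <- function() {
  cort <- c("frontal", "parietal", "temporal", "occipital", "insula")
  sub <- c("cerebral-wm", "cerebellar-wm", "cerebellar-cortex",
           "thalamus", "putamen", "pallidum")
  data.frame(
    id = 1:22,
    name = c(rep(cort, each = 2), rep(sub, each = 2)),
    hemisphere = rep(c("L", "R"), 11),
    class = c(rep("cortical", 10), rep("subcortical", 12)),
    stringsAsFactors = FALSE)
}

#' Brain mask of a phantom (any tissue or CSF present)
#' @param phantom a `tissue_phantom`.
#' @return logical 3-D array.
#' @export
brain_mask <- function(phantom) {
  phantom$tpm_gm + phantom$tpm_wm + phantom$tpm_csf > 0
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom %s, %d labelled voxels, %d ROIs>\n",
              paste(x$grid$shape, collapse = "x"),
              sum(x$labels > 0), nrow(x$roi_table)))
  invisible(x)
}

#' Ground-truth temperature field for a phantom subject
#'
#' The field is `base_temp` plus a fixed offset on subcortical-labelled
#' voxels plus spatially correlated noise (white noise smoothed with a
#' sigma-1 Gaussian and rescaled to unit SD before scaling by `noise_sd`).
#' The subcortical offset is applied crisply so that with `noise_sd = 0`
#' the subcortical minus cortical mean equals `subcortical_offset` exactly.
#' An axillary temperature reading is drawn for the subject unless supplied.
#'
#' @param phantom a `tissue_phantom`.
#' @param base_temp baseline brain temperature, degrees C.
#' @param subcortical_offset additive offset on subcortical regions, degrees C.
#' @param noise_sd SD of the spatially correlated noise, degrees C (>= 0).
#' @param seed integer RNG seed.
#' @param axillary_temp optional fixed axillary reading, degrees C; if NULL a
#'   reading is drawn around 36.33 (so the pulmonary-artery conversion lands
#'   near the 36.8 default inlet).
#' @return A `ground_truth`: list with `temperature` (3-D array, NA outside
#'   the brain) and `axillary_temp` (scalar in [34, 40]).
#' @export
make_truth_temperature <- function(phantom, base_temp = 37.0,
                                   subcortical_offset = 0.08,
                                   noise_sd = 0.05, seed = 1L,
                                   axillary_temp = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  set.seed(as.integer(seed))
  mask <- brain_mask(phantom)
  subcort_ids <- phantom$roi_table$id[phantom$roi_table$class == "subcortical"]
  temp <- array(base_temp, phantom$grid$shape)
  temp[phantom$labels %in% subcort_ids] <- base_temp + subcortical_offset
  if (noise_sd > 0) {
    noise <- gaussian_smooth(array(stats::rnorm(prod(phantom$grid$shape)),
                                   phantom$grid$shape), sigma = 1)
    noise <- noise / stats::sd(noise[mask])
    temp <- temp + noise_sd * noise
  }
  temp[!mask] <- NA_real_
  if (is.null(axillary_temp))
    axillary_temp <- min(40, max(34, round(stats::rnorm(1, 36.33, 0.25), 2)))
  if (axillary_temp < 34 || axillary_temp > 40)
    stop("axillary temperature outside the plausible range [34, 40] degrees C")
  structure(list(temperature = temp, axillary_temp = axillary_temp),
            class = "ground_truth")
}

#' Synthesize per-voxel spectra encoding a temperature field
#'
#' Every brain voxel receives three Lorentzian resonances — NAA at 2.01 ppm,
#' creatine at 3.03 ppm, and water at `naa_ppm + delta(T)` ppm, where
#' `delta(T)` is the exact inverse of [shift_to_temperature()] for that
#' voxel's GM fraction — plus complex Gaussian noise scaled so that the
#' water peak height divided by the per-channel noise SD equals `snr`.
#' Non-brain voxels receive noise only.
#'
#' @param phantom a `tissue_phantom`.
#' @param truth a `ground_truth` from [make_truth_temperature()].
#' @param cal a [calibration_params()] object; inverted to place the water line.
#' @param snr water peak height / noise SD; `Inf` for noise-free spectra.
#' @param linewidth_water_Hz,linewidth_met_Hz Lorentzian FWHM of the water
#'   and metabolite lines, Hz.
#' @param ppm_range,n_points spectral axis extent and sampling.
#' @param field_MHz proton frequency used for Hz/ppm conversion (default
#'   123.2, a 3 T system).
#' @param amplitudes named peak heights for water, naa, cre (a.u.).
#' @param naa_ppm,cre_ppm metabolite resonance positions, ppm.
#' @param seed integer RNG seed for the noise.
#' @return A `spectro_volume`: list with complex array `spectra`
#'   (nx, ny, nz, n_freq), `ppm_axis`, `field_MHz`.
#' @export
synth_spectra <- function(phantom, truth, cal = calibration_params(),
                          snr = 100, linewidth_water_Hz = 6,
                          linewidth_met_Hz = 4,
                          ppm_range = c(1.2, 5.6), n_points = 440L,
                          field_MHz = 123.2,
                          amplitudes = c(water = 10, naa = 1.5, cre = 1),
                          naa_ppm = 2.01, cre_ppm = 3.03, seed = 1L) {
  if (linewidth_water_Hz <= 0 || linewidth_met_Hz <= 0) stop("linewidths must be > 0")
  if (!(snr > 0)) stop("`snr` must be > 0 (possibly Inf)")
  shape <- phantom$grid$shape
  mask <- brain_mask(phantom)
  tvox <- truth$temperature[mask]
  if (any(!is.finite(tvox)) || any(tvox < 30 | tvox > 45))
    stop("temperature field leaves the calibration validity range [30, 45] degrees C")

  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  slope <- abs(cal$slope)
  gm <- phantom$tpm_gm[mask]
  delta <- cal$reference_shift -
    (tvox - cal$reference_temp - cal$gm_correction * gm) / slope
  water_ppm <- naa_ppm + delta

  lorentz <- function(centers, fwhm_Hz, amp) {
    hw <- (fwhm_Hz / field_MHz) / 2
    d <- outer(centers, ppm, function(cc, p) p - cc)
    denom <- d^2 + hw^2
    amp * hw^2 / denom + 1i * amp * hw * d / denom
  }

  set.seed(as.integer(seed))
  n_all <- prod(shape)
  spectra <- array(0+0i, c(n_all, n_points))
  if (is.finite(snr)) {
    nsd <- amplitudes[["water"]] / snr
    spectra[] <- complex(real = stats::rnorm(n_all * n_points, sd = nsd),
                         imaginary = stats::rnorm(n_all * n_points, sd = nsd))
  }
  widx <- which(mask)
  chunk <- 4096L
  for (s in seq(1L, length(widx), by = chunk)) {
    e <- min(s + chunk - 1L, length(widx))
    sel <- widx[s:e]; rel <- s:e
    sig <- lorentz(water_ppm[rel], linewidth_water_Hz, amplitudes[["water"]]) +
           lorentz(rep(naa_ppm, length(rel)), linewidth_met_Hz, amplitudes[["naa"]]) +
           lorentz(rep(cre_ppm, length(rel)), linewidth_met_Hz, amplitudes[["cre"]])
    spectra[sel, ] <- spectra[sel, , drop = FALSE] + sig
  }
  dim(spectra) <- c(shape, n_points)
  structure(list(spectra = spectra, ppm_axis = ppm, field_MHz = field_MHz),
            class = "spectro_volume")
}

#' Coarse arterial/venous seed trees for a phantom
#'
#' One arterial inlet root and one venous outlet root are placed near the
#' inferior face of the brain, each with two generations of coarse branches
#' reaching into the tissue interior — a stand-in for vessels segmented from
#' angiography/venography, to be densified by [rrt_augment()].
#'
#' @param phantom a `tissue_phantom`.
#' @param seed integer; jitters branch directions slightly.
#' @return A `vessel_tree` (see [vessel_tree()]) with two roots.
#' @export
make_vessel_seeds <- function(phantom, seed = 1L) {
  set.seed(as.integer(seed))
  shape <- phantom$grid$shape
  half <- (shape - 1) / 2
  cen <- (shape - 1) / 2
  norm_to_world <- function(u) {
    u <- matrix(u, ncol = 3)
    voxel_to_world(phantom$grid, sweep(u, 2, half, `*`) + matrix(cen, nrow(u), 3, byrow = TRUE))
  }
  jit <- function(n) stats::runif(n, -0.02, 0.02)

  build_side <- function(root_u, side, id0) {
    # two generation-1 branches per side, each splitting into two again
    u1a <- root_u + c(-0.25 * sign(root_u[1]), 0.22, 0.35) + jit(3)
    u1b <- root_u + c(-0.25 * sign(root_u[1]), -0.22, 0.35) + jit(3)
    u2 <- list(u1a + c(0.05, 0.18, 0.30) + jit(3),
               u1a + c(-0.15, 0.05, 0.32) + jit(3),
               u1b + c(0.05, -0.18, 0.30) + jit(3),
               u1b + c(-0.15, -0.05, 0.32) + jit(3))
    us <- rbind(root_u, u1a, u1b, do.call(rbind, u2))
    us[, 1] <- pmax(pmin(us[, 1], 0.7), -0.7)
    us[, 2] <- pmax(pmin(us[, 2], 0.7), -0.7)
    us[, 3] <- pmax(pmin(us[, 3], 0.7), -0.7)
    xyz <- norm_to_world(us)
    data.frame(id = id0 + 0:6, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               radius_um = c(1000, 600, 600, 350, 350, 350, 350),
               side = side,
               parent = c(NA, id0, id0, id0 + 1, id0 + 1, id0 + 2, id0 + 2),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(build_side(c(-0.15, 0, -0.75), "arterial", 1L),
                 build_side(c(0.15, 0, -0.75), "venous", 101L))
  tree <- vessel_tree(nodes)
  validate_vessel_tree(tree, phantom$grid)
  tree
}
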