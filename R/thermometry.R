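#' Chemical-shift thermometry calibration
#'
#' Parameters of the water-NAA chemical-shift thermometer. The water proton
#' resonance moves upfield by about 0.01 ppm per degree C while NAA is
#' temperature-insensitive, so the water-NAA separation encodes absolute
#' temperature. A larger separation means a lower temperature; `slope` is
#' the magnitude in degrees C per ppm. An optional additive grey-matter
#' correction (degrees C per unit GM fraction) absorbs the systematic
#' frequency difference between grey and white matter.
#'
#' @param reference_shift water-NAA separation (ppm) at `reference_temp`.
#' @param reference_temp reference temperature, degrees C (in [35, 39]).
#' @param slope magnitude of the calibration slope, degrees C per ppm
#'   (in [80, 120]; default 100, i.e. 0.01 ppm per degree C).
#' @param gm_correction degrees C added per unit GM fraction (default 0).
#' @return a `calibration_params` list.
#' @export
calibration_params <- function(reference_shift = 2.665, reference_temp = 37.0,
                               slope = 100, gm_correction = 0) {
  if (abs(slope) < 80 || abs(slope) > 120)
    stop("|slope| must lie in [80, 120] degrees C per ppm")
  if (reference_temp < 35 || reference_temp > 39)
    stop("`reference_temp` must lie in [35, 39] degrees C")
  structure(list(reference_shift = reference_shift,
                 reference_temp = reference_temp,
                 slope = slope, gm_correction = gm_correction),
            class = "calibration_params")
}

#' Spectral quality-control thresholds
#'
#' Four criteria; a voxel is kept only if it passes all of them with strict
#' inequalities: water linewidth < `water_lw_max` Hz, metabolite linewidth
#' < `met_lw_max` Hz, creatine amplitude CRLB < `crlb_cr_max` %, and a
#' robust outlier test with threshold `outlier_z_max`.
#'
#' @param water_lw_max,met_lw_max linewidth limits, Hz.
#' @param crlb_cr_max creatine Cramer-Rao lower bound limit, percent.
#' @param outlier_z_max robust z-score limit of the slice-wise outlier test.
#' @return a `qc_rules` list.
#' @export
qc_rules <- function(water_lw_max = 18, met_lw_max = 8,
                     crlb_cr_max = 15, outlier_z_max = 3) {
  vals <- c(water_lw_max, met_lw_max, crlb_cr_max, outlier_z_max)
  if (any(vals <= 0)) stop("all QC thresholds must be strictly positive")
  structure(list(water_lw_max = water_lw_max, met_lw_max = met_lw_max,
                 crlb_cr_max = crlb_cr_max, outlier_z_max = outlier_z_max),
            class = "qc_rules")
}

#' Convert a water-NAA separation to absolute temperature
#'
#' T = reference_temp + |slope| * (reference_shift - delta_ppm)
#'     + gm_correction * gm_fraction.
#' Separations outside the calibration validity window [2.3, 3.0] ppm give
#' NA (the voxel subsequently fails QC).
#'
#' @param delta_ppm water-NAA separation(s), ppm.
#' @param gm_fraction grey-matter fraction(s) in [0, 1].
#' @param cal a [calibration_params()].
#' @return temperature(s) in degrees C, NA where the separation is invalid.
#' @export
shift_to_temperature <- function(delta_ppm, gm_fraction = 0,
                                 cal = calibration_params()) {
  t_out <- cal$reference_temp + abs(cal$slope) * (cal$reference_shift - delta_ppm) +
    cal$gm_correction * gm_fraction
  t_out[!is.na(delta_ppm) & (delta_ppm < 2.3 | delta_ppm > 3.0)] <- NA_real_
  t_out[is.na(delta_ppm)] <- NA_real_
  t_out
}

#' Per-voxel Lorentzian peak fitting
#'
#' Fits one absorption-mode Lorentzian (centre, FWHM, amplitude) to the real
#' part of each voxel spectrum inside each requested ppm window by
#' Levenberg-Marquardt least squares with an analytic Jacobian. The creatine
#' amplitude's relative Cramer-Rao lower bound is computed from the Fisher
#' information of the fitted model at the residual noise level. Fit failure
#' in any window flags the voxel unusable rather than aborting the volume.
#'
#' @param vol a `spectro_volume` (see [synth_spectra()]).
#' @param resonances named list of ppm windows, each `c(lo, hi)` with at
#'   least 8 spectral points. Must contain `water`, `naa` and `cre` for the
#'   downstream temperature/QC stages.
#' @param mask optional logical array restricting which voxels are fitted;
#'   default: voxels whose peak real signal exceeds 5 robust noise SDs.
#' @return a `peak_fits`: per resonance, 3-D arrays `center` (ppm),
#'   `fwhm_Hz`, `amplitude`; plus `crlb_cre` (%), `converged` (logical),
#'   `noise_sd`, `field_MHz` and the fitted `mask`.
#' @export
fit_peaks <- function(vol,
                      resonances = list(naa = c(1.81, 2.21),
                                        cre = c(2.83, 3.23),
                                        water = c(4.30, 5.10)),
                      mask = NULL) {
  ppm <- vol$ppm_axis
  shape <- dim(vol$spectra)[1:3]
  n_all <- prod(shape)
  spec_re <- Re(vol$spectra)
  dim(spec_re) <- c(n_all, length(ppm))

  # robust noise estimate from a signal-free margin (outermost spectral points)
  edge <- c(1:8, (length(ppm) - 7):length(ppm))
  noise_sd_global <- stats::mad(spec_re[, edge])

  if (is.null(mask)) {
    peak <- matrixStats_rowMax(spec_re)
    mask <- array(peak > 5 * max(noise_sd_global, 1e-12), shape)
  }
  vox <- which(mask)

  windows <- lapply(resonances, function(w) which(ppm >= w[1] & ppm <= w[2]))
  bad <- vapply(windows, length, 1L) < 8L
  if (any(bad))
    stop("resonance window(s) ", paste(names(windows)[bad], collapse = ", "),
         " contain fewer than 8 spectral points")

  res <- lapply(resonances, function(w)
    list(center = array(NA_real_, shape), fwhm_Hz = array(NA_real_, shape),
         amplitude = array(NA_real_, shape)))
  crlb_cre <- array(NA_real_, shape)
  converged <- array(FALSE, shape)
  converged[vox] <- TRUE

  for (rn in names(resonances)) {
    idx <- windows[[rn]]
    p <- ppm[idx]
    fits <- fit_lorentzian_many(spec_re[vox, idx, drop = FALSE], p)
    res[[rn]]$center[vox] <- fits$center
    res[[rn]]$fwhm_Hz[vox] <- fits$fwhm_ppm * vol$field_MHz
    res[[rn]]$amplitude[vox] <- fits$amplitude
    converged[vox] <- converged[vox] & fits$converged
    if (rn == "cre") crlb_cre[vox] <- fits$crlb_amp_pct
  }

  structure(c(res, list(crlb_cre = crlb_cre, converged = converged,
                        noise_sd = noise_sd_global, field_MHz = vol$field_MHz,
                        mask = mask, shape = shape)),
            class = "peak_fits")
}

matrixStats_rowMax <- function(m) do.call(pmax, as.data.frame(m))

# Levenberg-Marquardt Lorentzian fits, one row of `y` per voxel.
# model: A * hw^2 / ((p - c)^2 + hw^2), hw = half width at half maximum (ppm)
fit_lorentzian_many <- function(y, p) {
  n <- nrow(y)
  out <- list(center = numeric(n), fwhm_ppm = numeric(n), amplitude = numeric(n),
              crlb_amp_pct = numeric(n), converged = logical(n))
  dp <- mean(diff(p))
  model <- function(par, pp) par[3] * par[2]^2 / ((pp - par[1])^2 + par[2]^2)
  jac <- function(par, pp) {
    d <- pp - par[1]; den <- d^2 + par[2]^2
    cbind(par[3] * par[2]^2 * 2 * d / den^2,
          par[3] * 2 * par[2] * d^2 / den^2,
          par[2]^2 / den)
  }
  for (i in seq_len(n)) {
    yi <- y[i, ]
    i0 <- which.max(yi)
    a0 <- yi[i0]
    half <- sum(yi > a0 / 2) * dp
    start <- c(p[i0], max(half / 2, dp / 2), max(a0, 1e-9))
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start,
                           fn = function(par) yi - model(par, p),
                           jac = function(par) -jac(par, p),
                           lower = c(min(p), dp / 10, 0),
                           upper = c(max(p), diff(range(p)), Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 80))),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4) || !all(is.finite(fit$par))) {
      out$converged[i] <- FALSE
      out$center[i] <- NA; out$fwhm_ppm[i] <- NA; out$amplitude[i] <- NA
      out$crlb_amp_pct[i] <- NA
      next
    }
    par <- fit$par
    out$converged[i] <- TRUE
    out$center[i] <- par[1]
    out$fwhm_ppm[i] <- 2 * par[2]
    out$amplitude[i] <- par[3]
    # CRLB of the amplitude from the Fisher information at the residual noise
    J <- jac(par, p)
    sigma <- sqrt(sum(fit$fvec^2) / max(1, length(p) - 3))
    cov_a <- tryCatch(sigma^2 * solve(crossprod(J))[3, 3],
                      error = function(e) NA_real_)
    out$crlb_amp_pct[i] <- if (is.na(cov_a) || cov_a < 0) NA_real_ else
      100 * sqrt(cov_a) / par[3]
  }
  out
}

#' Slice-wise robust spectral outlier test
#'
#' Within each axial slice, a voxel fails if its robust z-score
#' |value - median| / (1.4826 * MAD) exceeds `z_max`, computed over the
#' in-mask voxels of that slice. A degenerate slice (MAD = 0) passes
#' entirely.
#'
#' @param values 3-D array of per-voxel values (temperatures or frequencies).
#' @param mask logical array of voxels entering the test (>= 20 required).
#' @param z_max robust z threshold (default 3).
#' @return logical 3-D array: TRUE where the voxel passes (voxels outside
#'   `mask` are TRUE; they are excluded elsewhere).
#' @export
spectral_outlier_test <- function(values, mask, z_max = 3) {
  if (sum(mask, na.rm = TRUE) < 20)
    stop("outlier test requires at least 20 in-mask voxels")
  pass <- array(TRUE, dim(values))
  for (k in seq_len(dim(values)[3])) {
    mk <- mask[, , k]
    if (!any(mk)) next
    v <- values[, , k][mk]
    med <- stats::median(v, na.rm = TRUE)
    s <- 1.4826 * stats::median(abs(v - med), na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    z <- abs(values[, , k] - med) / s
    slice <- pass[, , k]
    slice[mk & !is.na(z) & z > z_max] <- FALSE
    pass[, , k] <- slice
  }
  pass
}

new_temperature_map <- function(grid, values, qc_mask, qc_report = list()) {
  structure(list(grid = grid, values = values, qc_mask = qc_mask,
                 qc_report = qc_report), class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  cat(sprintf("<temperature_map %s, %d QC-passing voxels, mean %.2f C>\n",
              paste(x$grid$shape, collapse = "x"), sum(x$qc_mask),
              mean(x$values[x$qc_mask])))
  invisible(x)
}

#' Four-criterion spectral quality filter
#'
#' A voxel is kept iff (strict inequalities throughout): water FWHM <
#' `water_lw_max` Hz, metabolite FWHM < `met_lw_max` Hz, creatine amplitude
#' CRLB < `crlb_cr_max` %, and it passes the slice-wise robust outlier test
#' on `values` (typically the temperature map). Non-converged fits and
#' voxels with undefined temperature fail. The report tabulates failures
#' per criterion among fitted voxels.
#'
#' @param fits a `peak_fits` from [fit_peaks()].
#' @param rules a [qc_rules()].
#' @param values optional 3-D array tested for outliers (and carried as the
#'   map values); defaults to the fitted water centre frequency.
#' @param grid optional [voxel_grid()] recorded on the returned map.
#' @param water,met names of the resonances used for the water and
#'   metabolite linewidth criteria.
#' @return a `temperature_map`: `values` (NA outside the mask), `qc_mask`,
#'   and `qc_report` with per-criterion failure counts.
#' @export
qc_filter <- function(fits, rules = qc_rules(), values = NULL, grid = NULL,
                      water = "water", met = "naa") {
  fitted <- fits$mask & fits$converged
  if (is.null(values)) values <- fits[[water]]$center
  defined <- fitted & !is.na(values)

  fails <- function(v, lim) fitted & (is.na(v) | v >= lim)
  f_water <- fails(fits[[water]]$fwhm_Hz, rules$water_lw_max)
  f_met <- fails(fits[[met]]$fwhm_Hz, rules$met_lw_max)
  f_crlb <- fails(fits$crlb_cre, rules$crlb_cr_max)
  pre_mask <- defined & !f_water & !f_met & !f_crlb

  outlier_pass <- if (sum(pre_mask) >= 20)
    spectral_outlier_test(values, pre_mask, rules$outlier_z_max)
  else array(TRUE, dim(values))
  f_out <- pre_mask & !outlier_pass

  qc_mask <- pre_mask & outlier_pass
  report <- list(
    n_fitted = sum(fitted), n_unconverged = sum(fits$mask & !fits$converged),
    fail_water_lw = sum(f_water, na.rm = TRUE),
    fail_met_lw = sum(f_met, na.rm = TRUE),
    fail_crlb = sum(f_crlb, na.rm = TRUE),
    fail_outlier = sum(f_out, na.rm = TRUE),
    fail_undefined = sum(fitted & is.na(values)),
    n_pass = sum(qc_mask))
  vals <- values
  vals[!qc_mask] <- NA_real_
  if (is.null(grid))  # placeholder unit grid (may be smaller than real volumes)
    grid <- structure(list(shape = dim(values), voxel_size = rep(1, 3),
                           affine = diag(4)), class = "voxel_grid")
  new_temperature_map(grid, vals, qc_mask, report)
}

#' Full thermometry stage: spectra to QC-filtered temperature map
#'
#' Fits the water, NAA and creatine resonances, converts the water-NAA
#' separation to temperature with the GM-fraction correction, and applies
#' the four-criterion quality filter.
#'
#' @param vol a `spectro_volume`.
#' @param phantom a `tissue_phantom` supplying the GM fraction and grid
#'   (optional; GM fraction 0 is used without it).
#' @param cal a [calibration_params()].
#' @param rules a [qc_rules()].
#' @param ... passed to [fit_peaks()] (e.g. `mask`, `resonances`).
#' @return a `temperature_map`.
#' @export
thermometry_map <- function(vol, phantom = NULL, cal = calibration_params(),
                            rules = qc_rules(), ...) {
  args <- list(...)
  if (is.null(args$mask) && !is.null(phantom)) args$mask <- brain_mask(phantom)
  fits <- do.call(fit_peaks, c(list(vol = vol), args))
  delta <- fits$water$center - fits$naa$center
  gm <- if (is.null(phantom)) 0 else phantom$tpm_gm
  temps <- shift_to_temperature(delta, gm, cal)
  grid <- if (is.null(phantom)) NULL else phantom$grid
  qc_filter(fits, rules, values = temps, grid = grid)
}
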