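test_that("noiseless Lorentzian parameters are recovered to high precision", {
  vol <- single_voxel_volume(center_ppm = 4.67, fwhm_Hz = 6, amp = 10)
  fits <- fit_peaks(vol, resonances = list(water = c(4.3, 5.1)),
                    mask = array(TRUE, c(1, 1, 1)))
  expect_true(fits$converged[1])
  expect_lt(abs(fits$water$center[1] - 4.67) / 4.67, 1e-6)
  expect_lt(abs(fits$water$fwhm_Hz[1] - 6) / 6, 1e-6)
  expect_lt(abs(fits$water$amplitude[1] - 10) / 10, 1e-6)
})

test_that("fitted FWHM in Hz is the ppm width scaled by the proton frequency", {
  vol <- single_voxel_volume(fwhm_Hz = 8, field_MHz = 123.2)
  fits <- fit_peaks(vol, resonances = list(water = c(4.3, 5.1)),
                    mask = array(TRUE, c(1, 1, 1)))
  expect_equal(fits$water$fwhm_Hz[1] / 123.2 * 123.2, fits$water$fwhm_Hz[1])
  expect_equal(fits$water$fwhm_Hz[1], 8, tolerance = 1e-6)
})

test_that("creatine CRLB scales linearly with the noise level", {
  # same creatine spectrum, noise SD halved -> CRLB halves (Fisher scaling);
  # averaged over seeds to tame residual-estimate noise
  ratios <- vapply(1:6, function(s) {
    v1 <- single_voxel_volume(center_ppm = 3.03, fwhm_Hz = 4, amp = 1,
                              noise_sd = 0.04, seed = s)
    v2 <- single_voxel_volume(center_ppm = 3.03, fwhm_Hz = 4, amp = 1,
                              noise_sd = 0.02, seed = s)
    f1 <- fit_peaks(v1, resonances = list(cre = c(2.83, 3.23)),
                    mask = array(TRUE, c(1, 1, 1)))
    f2 <- fit_peaks(v2, resonances = list(cre = c(2.83, 3.23)),
                    mask = array(TRUE, c(1, 1, 1)))
    f1$crlb_cre[1] / f2$crlb_cre[1]
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.35)
})

test_that("CRLB matches the Fisher information from numerical differentiation", {
  vol <- single_voxel_volume(center_ppm = 3.03, fwhm_Hz = 4, amp = 1,
                             noise_sd = 0.03, seed = 2)
  fits <- fit_peaks(vol, resonances = list(cre = c(2.83, 3.23)),
                    mask = array(TRUE, c(1, 1, 1)))
  # independent oracle: finite-difference Jacobian of the Lorentzian model
  ppm <- vol$ppm_axis
  idx <- ppm >= 2.83 & ppm <= 3.23
  p <- ppm[idx]
  y <- Re(vol$spectra[1, 1, 1, ])[idx]
  par <- c(fits$cre$center[1], fits$cre$fwhm_Hz[1] / 123.2 / 2,
           fits$cre$amplitude[1])
  mod <- function(q) q[3] * q[2]^2 / ((p - q[1])^2 + q[2]^2)
  J <- vapply(1:3, function(k) {
    h <- max(1e-7, abs(par[k]) * 1e-6)
    e <- numeric(3); e[k] <- h
    (mod(par + e) - mod(par - e)) / (2 * h)
  }, numeric(length(p)))
  sigma <- sqrt(sum((y - mod(par))^2) / (length(p) - 3))
  crlb_oracle <- 100 * sqrt(sigma^2 * solve(crossprod(J))[3, 3]) / par[3]
  expect_equal(fits$crlb_cre[1], crlb_oracle, tolerance = 1e-3)
})

test_that("shift-to-temperature calibration is affine with the documented errors", {
  cal <- calibration_params()
  expect_equal(shift_to_temperature(cal$reference_shift, 0, cal),
               cal$reference_temp)
  # a 0.006 ppm shift error maps to 0.6 degrees C, 0.0018 ppm to ~0.2
  t0 <- shift_to_temperature(cal$reference_shift, 0, cal)
  expect_equal(abs(shift_to_temperature(cal$reference_shift - 0.006, 0, cal) - t0), 0.6)
  expect_equal(round(abs(shift_to_temperature(cal$reference_shift - 0.0018, 0, cal) - t0), 1), 0.2)
  # exactly affine in delta and gm fraction
  cal_g <- calibration_params(gm_correction = 0.3)
  d <- seq(2.4, 2.9, by = 0.05)
  tt <- shift_to_temperature(d, 0.25, cal_g)
  expect_equal(diff(tt), rep(-100 * 0.05, length(d) - 1))
  expect_equal(shift_to_temperature(2.665, 1, cal_g) -
                 shift_to_temperature(2.665, 0, cal_g), 0.3)
  # out-of-validity separations are undefined
  expect_true(is.na(shift_to_temperature(2.2, 0, cal)))
  expect_true(is.na(shift_to_temperature(3.1, 0, cal)))
})

test_that("slice-wise outlier test matches its robust-z definition", {
  vals <- array(37, c(6, 6, 4))
  mask <- array(TRUE, dim(vals))
  expect_true(all(spectral_outlier_test(vals, mask)))  # MAD = 0: all pass

  set.seed(1)
  vals <- array(rnorm(6 * 6 * 4, 37, 0.1), dim(vals))
  vals[3, 3, 2] <- 37 + 10 * 0.1 * 5
  pass <- spectral_outlier_test(vals, mask, z_max = 3)
  expect_false(pass[3, 3, 2])

  # Gaussian tail rate: fail fraction approximately 2*(1 - pnorm(3))
  set.seed(7)
  big <- array(rnorm(50 * 50 * 2), c(50, 50, 2))
  frac <- mean(!spectral_outlier_test(big, array(TRUE, dim(big)), 3))
  expect_gt(frac, 0.0005)
  expect_lt(frac, 0.008)

  expect_error(spectral_outlier_test(vals, array(FALSE, dim(vals))), "20")
})

test_that("QC filter enumerates planted violations with strict thresholds", {
  # 10 voxels: 6 clean, one violation of each criterion, one double violation
  water <- c(10, 10, 18, 10, 10, 10, 10, 10, 25, 10)   # voxel 3 exactly at limit
  met <- c(4, 4, 4, 9, 4, 4, 4, 4, 4, 4)
  crlb <- c(5, 5, 5, 5, 20, 5, 5, 5, 30, 5)
  fits <- manual_fits(water, met, crlb)
  map <- qc_filter(fits, qc_rules(), values = array(37, c(1, 1, 10)))
  # survivors by hand: fail {3 (water = 18 not < 18), 4 (met), 5 (crlb), 9 (both)}
  expect_equal(sum(map$qc_mask), 6L)
  expect_equal(map$qc_report$fail_water_lw, 2L)
  expect_equal(map$qc_report$fail_met_lw, 1L)
  expect_equal(map$qc_report$fail_crlb, 2L)
  expect_false(map$qc_mask[1, 1, 3])
})

test_that("QC mask grows monotonically as thresholds loosen", {
  set.seed(3)
  n <- 40L
  fits <- manual_fits(runif(n, 5, 25), runif(n, 2, 12), runif(n, 1, 25),
                      shape = c(1L, 1L, n))
  vals <- array(rnorm(n, 37, 0.2), c(1, 1, n))
  base <- qc_filter(fits, qc_rules(), values = vals)$qc_mask
  for (loose in list(qc_rules(water_lw_max = 30), qc_rules(met_lw_max = 20),
                     qc_rules(crlb_cr_max = 40), qc_rules(outlier_z_max = 10))) {
    m <- qc_filter(fits, loose, values = vals)$qc_mask
    expect_true(all(m[base]))
  }
})

test_that("thermometry recovers the ground truth through the full chain", {
  ph <- fx_phantom()
  tr <- fx_truth()
  map <- fx_clean_fit()$map
  err <- abs(map$values - tr$temperature)
  expect_gt(sum(map$qc_mask), 1000)
  expect_lt(max(err[map$qc_mask]), 0.01)  # infinite-SNR round trip
})

test_that("temperature error scales inversely with spectral SNR", {
  ph <- fx_phantom()
  tr <- fx_truth()
  err_sd <- vapply(c(60, 120), function(s) {
    vol <- synth_spectra(ph, tr, snr = s, seed = 11L)
    map <- thermometry_map(vol, ph)
    sd((map$values - tr$temperature)[map$qc_mask])
  }, numeric(1))
  expect_equal(err_sd[1] / err_sd[2], 2, tolerance = 0.4)
})
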