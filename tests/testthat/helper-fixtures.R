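# shared fixtures, built once per test run

.fx <- new.env()

fx_phantom <- function() {
  if (is.null(.fx$ph)) .fx$ph <- make_phantom(c(16L, 16L, 16L), 6, seed = 1L)
  .fx$ph
}

fx_phantom20 <- function() {
  if (is.null(.fx$ph20)) .fx$ph20 <- make_phantom(c(20L, 20L, 20L), 5, seed = 1L)
  .fx$ph20
}

fx_truth <- function() {
  if (is.null(.fx$truth))
    .fx$truth <- make_truth_temperature(fx_phantom(), noise_sd = 0.1, seed = 2L)
  .fx$truth
}

# noiseless spectra + fits for the round-trip checks
fx_clean_fit <- function() {
  if (is.null(.fx$clean)) {
    ph <- fx_phantom()
    vol <- synth_spectra(ph, fx_truth(), snr = Inf)
    .fx$clean <- list(vol = vol, map = thermometry_map(vol, ph))
  }
  .fx$clean
}

# one solved tree-mode simulation on the 20^3 phantom
fx_sim <- function() {
  if (is.null(.fx$sim))
    .fx$sim <- simulate_brain_temperature(fx_phantom20(), n_terminals = 80L,
                                          seed = 1L)
  .fx$sim
}

# uniform pure-GM block on an n^3 grid (no phantom geometry), for analytic
# bioheat oracles
uniform_gm_block <- function(n = 10L, voxel = 5) {
  shape <- rep(as.integer(n), 3)
  structure(list(grid = voxel_grid(shape, voxel),
                 tpm_gm = array(1, shape), tpm_wm = array(0, shape),
                 tpm_csf = array(0, shape), labels = array(0L, shape),
                 roi_table = phantom_roi_table()),
            class = "tissue_phantom")
}

# single absorption Lorentzian spectro_volume at one voxel
single_voxel_volume <- function(center_ppm = 4.67, fwhm_Hz = 6, amp = 10,
                                noise_sd = 0, field_MHz = 123.2,
                                ppm_range = c(1.2, 5.6), n_points = 440L,
                                seed = 1L) {
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  hw <- (fwhm_Hz / field_MHz) / 2
  d <- ppm - center_ppm
  spec <- amp * hw^2 / (d^2 + hw^2) + 1i * amp * hw * d / (d^2 + hw^2)
  if (noise_sd > 0) {
    set.seed(seed)
    spec <- spec + complex(real = rnorm(n_points, sd = noise_sd),
                           imaginary = rnorm(n_points, sd = noise_sd))
  }
  structure(list(spectra = array(spec, c(1, 1, 1, n_points)),
                 ppm_axis = ppm, field_MHz = field_MHz),
            class = "spectro_volume")
}

# hand-built peak_fits object for QC enumeration fixtures
manual_fits <- function(water_fwhm, naa_fwhm, crlb, shape = NULL) {
  n <- length(water_fwhm)
  if (is.null(shape)) shape <- c(1L, 1L, n)
  arr <- function(v) array(v, shape)
  structure(list(
    water = list(center = arr(4.675), fwhm_Hz = arr(water_fwhm), amplitude = arr(10)),
    naa = list(center = arr(2.01), fwhm_Hz = arr(naa_fwhm), amplitude = arr(1.5)),
    cre = list(center = arr(3.03), fwhm_Hz = arr(naa_fwhm), amplitude = arr(1)),
    crlb_cre = arr(crlb), converged = arr(TRUE), noise_sd = 0.01,
    field_MHz = 123.2, mask = arr(TRUE), shape = shape),
    class = "peak_fits")
}
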