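#' End-to-end self-consistency experiment
#'
#' Runs the biophysical solver once on a default phantom, then emulates a
#' cohort of repeated MR measurements: for each synthetic subject the
#' pseudo-measurement is the model field plus i.i.d. Gaussian voxel noise of
#' SD `measurement_noise_sd`. The full agreement stage is then applied —
#' voxel-wise within-threshold fraction per subject, regional means, pooled
#' Z-standardization and Bland-Altman limits over the subjects x regions
#' design. With noise SD 0.3 degrees C and threshold 0.8 degrees C the
#' expected within-threshold fraction is 2*pnorm(0.8/0.3) - 1 (about
#' 99.2 %), and about 95 % of pairs fall inside 1.96-SD limits of
#' agreement, so the experiment checks the whole compare stage against
#' closed-form expectations.
#'
#' @param shape,voxel_size phantom geometry (default 24^3 at 5 mm).
#' @param n_subjects number of synthetic subjects (default 30).
#' @param measurement_noise_sd SD of the pseudo-measurement noise, degrees C.
#' @param threshold voxel agreement threshold, degrees C.
#' @param loa_multiplier Bland-Altman limit half-width in SD units.
#' @param n_terminals RRT terminals per side for the solver run.
#' @param seed integer RNG seed.
#' @return list: `within_threshold_pct` (mean over subjects),
#'   `per_subject_within_pct`, `bland_altman` (pooled Z differences),
#'   `n_points`, `n_voxels`, `contrasts_model`, `audit`, `field`.
#' @export
self_consistency_experiment <- function(shape = c(24L, 24L, 24L),
                                        voxel_size = 5,
                                        n_subjects = 30L,
                                        measurement_noise_sd = 0.3,
                                        threshold = 0.8,
                                        loa_multiplier = 1.96,
                                        n_terminals = 100L,
                                        seed = 1L) {
  phantom <- make_phantom(shape, voxel_size, seed)
  sim <- simulate_brain_temperature(phantom, n_terminals = n_terminals,
                                    seed = seed)
  model <- sim$field$tissue
  model_reg <- regional_stats(model, phantom)
  keep <- !model_reg$excluded & !model_reg$missing

  set.seed(as.integer(seed) + 1L)
  nb <- sum(!is.na(model))
  wt <- numeric(n_subjects)
  mr_means <- matrix(NA_real_, n_subjects, sum(keep))
  for (j in seq_len(n_subjects)) {
    pseudo <- model
    pseudo[!is.na(model)] <- model[!is.na(model)] +
      stats::rnorm(nb, sd = measurement_noise_sd)
    wt[j] <- within_threshold(model, pseudo, threshold)
    mr_means[j, ] <- regional_stats(pseudo, phantom)$mean[keep]
  }
  meta <- model_reg[keep, c("id", "name", "hemisphere", "class")]
  rm_model <- regional_matrix(matrix(rep(model_reg$mean[keep], each = n_subjects),
                                     n_subjects), meta)
  rm_mr <- regional_matrix(mr_means, meta)
  ba <- bland_altman(zscore_regions(rm_model), zscore_regions(rm_mr),
                     loa_multiplier)
  list(within_threshold_pct = mean(wt), per_subject_within_pct = wt,
       bland_altman = ba, n_points = n_subjects * sum(keep),
       n_voxels = nb, contrasts_model = regional_contrasts(rm_model),
       audit = sim$audit, field = sim$field)
}
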