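#' Default pipeline configuration
#'
#' Nested list with one section per stage; every default matches the
#' corresponding function defaults. Unknown keys in a supplied or loaded
#' configuration are errors, guarding against silent typos.
#'
#' @param ... named sections (e.g. `phantom = list(shape = c(24, 24, 24))`)
#'   merged over the defaults.
#' @return a `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    phantom = list(shape = c(32L, 32L, 32L), voxel_size = 4,
                   base_temp = 37.0, subcortical_offset = 0.08,
                   noise_sd = 0.05, axillary_temp = NULL),
    spectra = list(snr = 100, linewidth_water_Hz = 6, linewidth_met_Hz = 4,
                   field_MHz = 123.2, n_points = 440L),
    calibration = list(reference_shift = 2.665, reference_temp = 37.0,
                       slope = 100, gm_correction = 0),
    qc = list(water_lw_max = 18, met_lw_max = 8, crlb_cr_max = 15,
              outlier_z_max = 3),
    vascular = list(cbf_gm = 60, cbf_wm = 22, tissue_density = 1.045,
                    n_terminals = 150L, step_mm = NULL,
                    terminal_diameter_um = 7, murray_exponent = 3,
                    nusselt = 4, mode = "tree"),
    boundary = list(inlet_mode = "fixed", inlet_temp = 36.8,
                    axillary_temp = NULL, scalp_mode = "robin",
                    ambient_temp = 24, surface_coefficient = 4),
    compare = list(threshold = 0.8, loa_multiplier = 1.96,
                   smooth = FALSE, min_dim_mm = c(4.4, 4.4, 5.6)))
  user <- list(...)
  cfg <- merge_config(defaults, user, path = "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, path) {
  if (!length(user)) return(base)
  nm <- names(user)
  if (is.null(nm) || any(nm == ""))
    stop("configuration entries must be named (at '", path, "')")
  unknown <- setdiff(nm, names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration section '", k, "' must be a list")
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                paste0(path, ".", k))
    } else {
      base[k] <- user[k]  # keeps explicit NULLs
    }
  }
  base
}

#' Read / write a pipeline configuration file
#'
#' YAML with one section per stage; keys are validated against
#' [run_config()] and unknown keys are errors.
#'
#' @param path YAML file.
#' @param config a `run_config`.
#' @return `read_run_config` a `run_config`; `write_run_config` the path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# FNV-1a hash of the serialized configuration, for run provenance
# (32-bit arithmetic kept exact in doubles by splitting the multiply)
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      null = "null", digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full phantom-to-agreement pipeline
#'
#' Executes the two independent arms — phantom -> spectra -> thermometry
#' (the emulated MR measurement) and phantom -> vasculature -> bioheat (the
#' biophysical prediction) — then the agreement stage, writing all
#' intermediate artifacts, a machine-readable summary JSON and a log into
#' `out_dir`. Any stage failure aborts with the stage name; partial outputs
#' are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, the summary list (also written as summary.json).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("run started %s\nseed %d\nconfig hash %s\nR %s, brainheat %s\n",
              format(Sys.time()), config$seed, config_hash(config),
              getRversion(),
              as.character(utils::packageVersion("brainheat"))),
      file = logf)
  stage <- function(name, expr) {
    log_line("stage %s ...", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  write_run_config(config, file.path(out_dir, "config.yaml"))
  seed <- as.integer(config$seed)

  ph <- stage("phantom", {
    p <- make_phantom(config$phantom$shape, config$phantom$voxel_size, seed)
    write_phantom(p, file.path(out_dir, "phantom"))
    p
  })
  truth <- stage("phantom", {
    tr <- make_truth_temperature(ph, config$phantom$base_temp,
                                 config$phantom$subcortical_offset,
                                 config$phantom$noise_sd, seed,
                                 axillary_temp = config$phantom$axillary_temp)
    write_ground_truth(tr, ph$grid, file.path(out_dir, "phantom"))
    tr
  })
  cal <- do.call(calibration_params, config$calibration)
  vol <- stage("spectra", {
    v <- do.call(synth_spectra,
                 c(list(phantom = ph, truth = truth, cal = cal, seed = seed),
                   config$spectra))
    saveRDS(list(ppm_axis = v$ppm_axis, field_MHz = v$field_MHz,
                 spectra = v$spectra),
            file.path(out_dir, "spectra.rds"))
    v
  })
  t_mr <- stage("thermometry", {
    m <- thermometry_map(vol, ph, cal, do.call(qc_rules, config$qc))
    if (isTRUE(config$compare$smooth)) m <- gaussian_smooth(m)
    write_temperature_map(m, file.path(out_dir, "thermometry"), "mr")
    m
  })
  bc_args <- config$boundary
  if (bc_args$inlet_mode == "axillary" && is.null(bc_args$axillary_temp))
    bc_args$axillary_temp <- truth$axillary_temp
  bc <- do.call(boundary_conditions, bc_args)
  sim <- stage("bioheat", {
    s <- do.call(simulate_brain_temperature,
                 c(list(phantom = ph, bc = bc, seed = seed),
                   config$vascular))
    if (!is.null(s$tree)) {
      write_swc(s$tree, file.path(out_dir, "vessels.swc"))
      write_flows(s$flows, file.path(out_dir, "flows.csv"))
      write_volume(s$demand$demand, ph$grid,
                   file.path(out_dir, "demand.nii.gz"))
    }
    s
  })
  t_model <- new_temperature_map(ph$grid, sim$field$tissue,
                                 !is.na(sim$field$tissue),
                                 list(n_pass = sum(!is.na(sim$field$tissue))))
  if (isTRUE(config$compare$smooth)) t_model <- gaussian_smooth(t_model)
  write_temperature_map(t_model, file.path(out_dir, "bioheat"), "model")

  summary <- stage("compare", {
    thr <- config$compare$threshold
    wt <- within_threshold(t_model, t_mr, thr)
    reg_model <- regional_stats(t_model, ph, config$compare$min_dim_mm)
    reg_mr <- regional_stats(t_mr, ph, config$compare$min_dim_mm)
    keep <- !reg_model$excluded & !reg_model$missing & !reg_mr$missing
    if (sum(keep) < 3) stop("fewer than 3 usable regions")
    rm_model <- regional_matrix(matrix(reg_model$mean[keep], 1),
                                reg_model[keep, c("id", "name", "hemisphere", "class")])
    rm_mr <- regional_matrix(matrix(reg_mr$mean[keep], 1),
                             reg_mr[keep, c("id", "name", "hemisphere", "class")])
    ba <- bland_altman(zscore_regions(rm_model), zscore_regions(rm_mr),
                       config$compare$loa_multiplier)
    reg <- data.frame(reg_model[keep, c("id", "name", "hemisphere", "class")],
                      t_model = reg_model$mean[keep], t_mr = reg_mr$mean[keep],
                      diff = reg_model$mean[keep] - reg_mr$mean[keep])
    utils::write.csv(reg, file.path(out_dir, "regional.csv"), row.names = FALSE)
    utils::write.csv(data.frame(mean = ba$mean, diff = ba$diff),
                     file.path(out_dir, "bland_altman.csv"), row.names = FALSE)
    ctr <- regional_contrasts(rm_model)
    list(config_hash = config_hash(config), seed = seed,
         n_qc_voxels = sum(t_mr$qc_mask),
         within_threshold_pct = wt,
         bland_altman = ba[c("bias", "sd", "loa_low", "loa_high",
                             "fraction_within_loa_pct", "n")],
         contrasts_model = ctr,
         venous_out_C = sim$audit$venous_out_C,
         arterial_in_C = sim$audit$arterial_in_C,
         energy_imbalance_rel = sim$audit$relative_imbalance,
         mean_model_C = mean(t_model$values[t_model$qc_mask]),
         mean_mr_C = mean(t_mr$values[t_mr$qc_mask]))
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("run complete")
  invisible(summary)
}
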