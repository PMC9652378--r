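#' Write phantom volumes to disk
#'
#' One NIfTI per tissue probability map, an integer label volume, and the
#' ROI table as CSV (id, name, hemisphere, class). The grid affine is
#' stored in every NIfTI header.
#'
#' @param phantom a `tissue_phantom`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("tpm_gm", "tpm_wm", "tpm_csf", "labels")) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(phantom[[nm]], phantom$grid, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "roi_table.csv")
  utils::write.csv(phantom$roi_table, f, row.names = FALSE)
  invisible(c(files, f))
}

#' Write a 3-D array as NIfTI with a grid's affine
#' @param values 3-D array.
#' @param grid a [voxel_grid()].
#' @param path output .nii or .nii.gz path.
#' @return invisibly the path.
#' @export
write_volume <- function(values, grid, path) {
  img <- RNifti::asNifti(values)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into an array plus voxel grid
#' @param path NIfTI file.
#' @return list(values, grid).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- voxel_grid(dim(img), vs, origin = aff[1:3, 4])
  grid$affine <- unclass(aff)
  list(values = array(as.numeric(img), dim(img)), grid = grid)
}

#' Write a temperature map (values + QC mask + report)
#' @param map a `temperature_map`.
#' @param dir output directory.
#' @param prefix file prefix.
#' @return invisibly the files written.
#' @export
write_temperature_map <- function(map, dir, prefix = "t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- map$values
  vals[!map$qc_mask] <- NA_real_
  f1 <- file.path(dir, paste0(prefix, "_temperature.nii.gz"))
  f2 <- file.path(dir, paste0(prefix, "_qcmask.nii.gz"))
  f3 <- file.path(dir, paste0(prefix, "_qc_report.json"))
  write_volume(vals, map$grid, f1)
  write_volume(array(as.numeric(map$qc_mask), dim(map$qc_mask)), map$grid, f2)
  jsonlite::write_json(map$qc_report, f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}

#' Write ground truth (temperature NIfTI + JSON sidecar with the axillary reading)
#' @param truth a `ground_truth`.
#' @param grid the phantom grid.
#' @param dir output directory.
#' @return invisibly the files written.
#' @export
write_ground_truth <- function(truth, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "truth_temperature.nii.gz")
  f2 <- file.path(dir, "truth_temperature.json")
  write_volume(truth$temperature, grid, f1)
  jsonlite::write_json(list(axillary_temp = truth$axillary_temp), f2,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

#' Write per-segment flows as CSV
#' @param flows a `flow_solution`.
#' @param path output CSV.
#' @return invisibly the path.
#' @export
write_flows <- function(flows, path) {
  utils::write.csv(flows$flows, path, row.names = FALSE)
  invisible(path)
}
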