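#' Write a label or count volume as NIfTI-1
#'
#' Voxel spacing is stored in the NIfTI header (`pixdim`).
#'
#' @param vol A [label_volume()] or [count_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume") || inherits(vol, "count_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_volume_nifti()]
#'
#' @param path Path to the NIfTI file.
#' @param type `"count"` (numeric) or `"label"` (integer).
#' @return A [count_volume()] or [label_volume()].
#' @export
read_volume_nifti <- function(path, type = c("count", "label")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  vx <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(img), dim = dim(img))
  if (type == "label") {
    storage.mode(arr) <- "integer"
    label_volume(arr, vx)
  } else {
    count_volume(arr, vx)
  }
}

#' Write a measurement table to CSV
#'
#' @param table A validated measurement table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  validate_measurement_table(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format measurement table from CSV
#'
#' @param path CSV path with columns patient, reviewer, assessment, method,
#'   endpoint, value and optionally units.
#' @return A validated measurement table data frame.
#' @export
read_measurement_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_measurement_table(tab)
  tab
}

#' Write a study configuration as YAML
#'
#' @param config A [study_config()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' @param path YAML path written by [write_study_config()].
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(study_config, x)
}
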