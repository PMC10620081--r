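# File interchange: NIfTI volumes for maps, YAML for configs, CSV for
# tables. Thin wrappers over RNifti / yaml / write.csv.

#' Write a 3D or 4D array as NIfTI
#'
#' @param arr numeric array (3D map or 4D, e.g. a 3-component field).
#' @param spacing voxel spacing, mm (length 3).
#' @param path output `.nii` path.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- spacing
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by this package
#' @param path `.nii` path.
#' @return list with `data` (array) and `spacing` (mm).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Write phantom volumes (labels, parcels, orientation) as NIfTI
#'
#' @param ph a phantom; `dir` output directory.
#' @return character vector of files written.
#' @export
write_phantom_nifti <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "labels.nii")
  write_nifti_volume(ph$labels, ph$spacing, f); files <- c(files, f)
  utils::write.csv(ph$tissue_table, file.path(dir, "tissues.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(dir, "tissues.csv"))
  if (!is.null(ph$parcels)) {
    f <- file.path(dir, "parcels.nii")
    write_nifti_volume(ph$parcels, ph$spacing, f); files <- c(files, f)
  }
  if (!is.null(ph$orientation)) {
    f <- file.path(dir, "orientation.nii")
    orient <- ph$orientation
    orient[is.na(orient)] <- 0
    write_nifti_volume(orient, ph$spacing, f); files <- c(files, f)
  }
  files
}

#' Write an exposure map pair as NIfTI
#' @param ex a [exposure_maps()] result; `dir` output directory;
#'   `prefix` file-name prefix.
#' @return character vector of files written.
#' @export
write_exposure_nifti <- function(ex, dir, prefix = "exposure") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_eam.nii"))
  f2 <- file.path(dir, paste0(prefix, "_eabs.nii"))
  eam <- ex$eam; eam[is.na(eam)] <- 0
  eabs <- ex$eabs; eabs[is.na(eabs)] <- 0
  write_nifti_volume(eam, ex$spacing, f1)
  write_nifti_volume(eabs, ex$spacing, f2)
  c(f1, f2)
}

#' Read / write a run configuration as YAML
#' @param config a run-config list; `path` YAML file path.
#' @return `read_config_yaml` returns the config list.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)
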