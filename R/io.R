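# Phantom and field I/O: NIfTI volumes (integer labels or floating-point
# potentials, spacing in the header) with a JSON sidecar for the label
# table, heart geometry and electrode solids.

#' Write a phantom to NIfTI + JSON sidecar
#'
#' @param phantom a `voxel_phantom`.
#' @param path output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json`.
#' @param electrodes optional `electrode_set` recorded in the sidecar.
#' @return invisibly, the two file paths.
#' @export
write_phantom_nifti <- function(phantom, path, electrodes = NULL) {
  img <- RNifti::asNifti(phantom$labels,
                         pixdim = rep(phantom$spacing, 3))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii)
  side <- list(
    spacing_mm = phantom$spacing,
    origin_mm = phantom$origin,
    label_names = as.list(phantom$label_names),
    myocardial_labels = phantom$myocardial_labels,
    torso = unclass(phantom$torso),
    heart = unclass(phantom$heart),
    heart_info = phantom$heart_info)
  if (!is.null(electrodes)) {
    side$electrodes <- list(
      config_name = electrodes$config_name,
      shocking = electrodes$shocking,
      ground = electrodes$ground)
  }
  js <- paste0(path, ".json")
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(nifti = nii, sidecar = js))
}

#' Read a phantom written by [write_phantom_nifti()]
#'
#' @param path path without extension.
#' @return a `voxel_phantom`.
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii.gz"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim = dim(img))
  torso <- structure(side$torso, class = "torso_params")
  heart <- structure(side$heart, class = "heart_params")
  hinfo <- side$heart_info
  for (nm in c("apex", "base_c", "dirn", "e1", "e2", "svc_xy", "svc_z")) {
    if (!is.null(hinfo[[nm]])) hinfo[[nm]] <- as.numeric(hinfo[[nm]])
  }
  structure(list(labels = labels, spacing = side$spacing_mm,
                 origin = as.numeric(side$origin_mm),
                 label_names = unlist(side$label_names),
                 myocardial_labels = as.integer(side$myocardial_labels),
                 torso = torso, heart = heart, heart_info = hinfo),
            class = "voxel_phantom")
}

#' Export a potential field (or any per-voxel scalar) as NIfTI
#'
#' @param field a `potential_field`.
#' @param path output path without extension; writes `<path>.nii.gz` and a
#'   JSON boundary record.
#' @return invisibly, the file paths.
#' @export
write_field_nifti <- function(field, path) {
  img <- RNifti::asNifti(field$phi, pixdim = rep(field$spacing, 3))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii)
  js <- paste0(path, ".json")
  jsonlite::write_json(list(mode = field$mode,
                            boundary_record = field$boundary_record,
                            residual = field$residual,
                            iterations = field$iterations),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(nifti = nii, record = js))
}

#' Export the fibre field as a 3-component NIfTI volume
#'
#' @param fibres a `fibre_field`.
#' @param path output path without extension.
#' @param spacing voxel spacing of the parent phantom, mm.
#' @return invisibly, the file path.
#' @export
write_fibres_nifti <- function(fibres, path, spacing) {
  d <- fibres$dim
  vol <- array(0, c(d, 3))
  n <- prod(d)
  for (k in 1:3) vol[fibres$myo_idx + (k - 1) * n] <- fibres$fibre[, k]
  img <- RNifti::asNifti(vol, pixdim = c(rep(spacing, 3), 1))
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii)
  invisible(nii)
}
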