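# NIfTI input/output for real contrast volumes and label images.

#' Build a signal matrix from NIfTI contrast volumes
#'
#' Reads per-subject (and per-contrast) 3D contrast images, flattens them
#' through a gray-matter mask, and assembles the n x Q signal matrix with
#' a 6-connectivity adjacency over the in-mask voxels.
#'
#' @param files character vector of NIfTI file paths, one volume per
#'   (subject, contrast) image.
#' @param mask_file path to a NIfTI mask volume (non-zero = in mask).
#' @param subject integer vector, subject of each file.
#' @param contrast integer vector, contrast of each file (default: one
#'   contrast).
#'
#' @return A list with `signal` (a [parcel_signal()]) and `adjacency`
#'   (a [grid_adjacency()] over the mask at 6-connectivity).
#' @export
signal_from_nifti <- function(files, mask_file, subject, contrast = NULL) {
  mask_img <- RNifti::readNifti(mask_file)
  mask <- array(as.vector(mask_img) != 0, dim = dim(mask_img))
  adjacency <- grid_adjacency(mask = mask)
  vox <- which(mask)
  values <- t(vapply(files, function(f) {
    img <- RNifti::readNifti(f)
    if (!all(dim(img) == dim(mask)))
      stop_bad_arg("volume %s does not match the mask dimensions", f)
    as.vector(img)[vox]
  }, numeric(length(vox))))
  rownames(values) <- NULL
  signal <- parcel_signal(values, subject = subject, contrast = contrast,
                          coords = adjacency$coords)
  list(signal = signal, adjacency = adjacency)
}

#' Write a parcellation as a NIfTI label volume
#'
#' Labels 1..K are written into the mask voxels, background 0, using the
#' mask's header geometry.
#'
#' @param parcellation a [new_parcellation()] or integer labeling over
#'   the in-mask voxels.
#' @param mask_file path to the mask volume that defined the voxel set.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_parcellation_nifti <- function(parcellation, mask_file, path) {
  labels <- if (inherits(parcellation, "parcellation"))
    parcellation$labels else as.integer(parcellation)
  mask_img <- RNifti::readNifti(mask_file)
  mask <- as.vector(mask_img) != 0
  if (sum(mask) != length(labels))
    stop_bad_arg("labeling covers %d voxels but the mask has %d",
                 length(labels), sum(mask))
  out <- array(0L, dim = dim(mask_img))
  out[which(mask)] <- labels
  img <- RNifti::asNifti(out, reference = mask_img)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a label volume as a voxel labeling over a mask
#'
#' Restricts an integer NIfTI label volume (e.g. a resampled atlas) to
#' the in-mask voxels, so that the resulting labeling can be scored with
#' [fit_parcellation_model()]. Background voxels (label 0) inside the
#' mask are assigned their own parcel label.
#'
#' @param label_file path to the label volume.
#' @param mask_file path to the mask volume.
#' @return Integer labeling over the in-mask voxels.
#' @export
read_labels_nifti <- function(label_file, mask_file) {
  lab_img <- RNifti::readNifti(label_file)
  mask_img <- RNifti::readNifti(mask_file)
  if (!all(dim(lab_img) == dim(mask_img)))
    stop_bad_arg("label volume does not match the mask dimensions")
  labels <- as.vector(lab_img)[as.vector(mask_img) != 0]
  relabel_first_occurrence(as.integer(round(labels)))
}
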