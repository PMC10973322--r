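## NIfTI and CSV round trips.

#' Write a CTVolume as NIfTI-1
#'
#' HU are stored as int16 with the voxel spacing in the header.
#'
#' @param volume A [CTVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  img <- RNifti::asNifti(huData(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a CTVolume from NIfTI-1
#'
#' @param path NIfTI file.
#' @param kneeToAnkle Asserted z-axis convention of the file (slice 1 at
#'   the knee); stored on the returned object.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path, kneeToAnkle = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 3)
    stop("malformed NIfTI header: expected a 3D volume in ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3 || any(sp[1:3] <= 0))
    stop("malformed NIfTI header: non-positive voxel spacing in ", path)
  ctVolume(arr, spacing = sp[1:3], kneeToAnkle = kneeToAnkle)
}

#' Write a MuscleMask as NIfTI-1 (uint8)
#'
#' @param mask A [MuscleMask-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "MuscleMask"))
  img <- RNifti::asNifti(array(as.integer(maskData(mask)),
                               dim(maskData(mask))))
  RNifti::pixdim(img) <- voxelSpacing(mask)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a MuscleMask from NIfTI-1
#'
#' Values other than 0/1 are rejected.
#'
#' @param path NIfTI file.
#' @return A [MuscleMask-class].
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (length(dim(arr)) != 3)
    stop("malformed NIfTI header: expected a 3D mask in ", path)
  if (!all(arr %in% c(0, 1)))
    stop("mask is not binary: ", path)
  sp <- RNifti::pixdim(img)
  muscleMask(arr == 1, spacing = sp[1:3])
}

#' Write a feature table as CSV
#'
#' One row per subject (or subject/region); column order is preserved and
#' numeric values round-trip at full double precision.
#'
#' @param table A data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path.
#' @param required Optional character vector of column names that must be
#'   present; missing ones raise a named-column error.
#' @return A data.frame.
#' @export
readFeatureTable <- function(path, required = NULL) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(tab))
    if (length(missing))
      stop("missing column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
  }
  tab
}
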