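# NIfTI-1 I/O. Geometry is taken from the sform/qform affine; only
# axis-aligned affines (diagonal up to axis permutation and sign flips) are
# supported, since the downstream volume and centroid arithmetic assumes an
# orthogonal lattice. Spacing is recovered as the column norms of the 3x3
# part and the origin as the translation; centroids are therefore expressed
# in an index-aligned frame with positive steps, which leaves every
# distance-, volume- and SUV-derived metric unchanged under flips and
# permutations.

nifti_geometry <- function(img, path) {
  d <- dim(img)
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) != 3L) {
    abort(sprintf("expected 3D volume in '%s' (found dimensions %s).",
                  path, paste(dim(img), collapse = "x")))
  }
  aff <- RNifti::xform(img)
  m <- aff[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(m^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort(sprintf("non-positive voxel spacing in '%s'.", path))
  }
  dominant <- integer(3)
  for (j in 1:3) {
    nz <- which(abs(m[, j]) > 1e-4 * spacing[j])
    if (length(nz) != 1L) {
      abort(sprintf(
        "unsupported oblique affine in '%s': only axis-aligned geometry (axis permutations and flips) is handled.",
        path))
    }
    dominant[j] <- nz
  }
  if (anyDuplicated(dominant)) {
    abort(sprintf("degenerate affine in '%s': two image axes map to the same world axis.", path))
  }
  vals <- as.vector(as.array(img)) # drop niftiImage attributes
  dim(vals) <- d
  list(values = vals, spacing = as.numeric(spacing),
       origin = as.numeric(aff[1:3, 4]))
}

check_readable <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("file not found: '%s'.", paste(path, collapse = ", ")))
  }
  invisible(path)
}

#' Read an SUV volume or a segmentation mask from a NIfTI-1 file
#'
#' `read_suv_volume()` loads a 3D scalar image whose voxel values are
#' body-weight SUV; values pass through unchanged. `read_mask()` loads a
#' binary lesion segmentation on the same lattice. Both take spacing and
#' origin from the file's affine (voxel-centre convention, 0-based indices).
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param patient_id Identifier attached to the result; defaults to the
#'   file name without extension.
#' @param reader_id Identifier of the reader who produced the mask.
#' @param binarize If `TRUE`, any voxel value greater than 0.5 becomes
#'   foreground (useful for masks stored as 0/255). If `FALSE` (default)
#'   the file must contain only the values 0 and 1.
#' @return A [suv_volume()] or [seg_mask()].
#' @seealso [write_suv_volume()], [write_mask()]
#' @export
read_suv_volume <- function(path, patient_id = NULL) {
  check_readable(path)
  geo <- nifti_geometry(RNifti::readNifti(path), path)
  suv_volume(geo$values, geo$spacing, geo$origin,
             patient_id = patient_id %||% strip_nii(path))
}

#' @rdname read_suv_volume
#' @export
read_mask <- function(path, reader_id = "reader", patient_id = NULL,
                      binarize = FALSE) {
  check_readable(path)
  geo <- nifti_geometry(RNifti::readNifti(path), path)
  vals <- geo$values
  if (binarize) {
    vals <- array(as.integer(vals > 0.5), dim = dim(vals))
  } else if (!all(vals %in% c(0, 1))) {
    abort(sprintf(
      "mask '%s' contains values other than 0/1; pass binarize = TRUE to threshold at > 0.5.",
      path))
  }
  seg_mask(vals, geo$spacing, geo$origin,
           patient_id = patient_id %||% strip_nii(path),
           reader_id = reader_id)
}

strip_nii <- function(path) sub("\\.nii(\\.gz)?$", "", basename(path))

nifti_from <- function(x, datatype) {
  img <- RNifti::asNifti(x$values)
  aff <- diag(4)
  diag(aff)[1:3] <- x$spacing
  aff[1:3, 4] <- x$origin
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write an SUV volume or a segmentation mask to a NIfTI-1 file
#'
#' Volumes are stored as 64-bit floats (exact round trip); masks as
#' unsigned 8-bit integers. The affine encodes spacing and origin with a
#' positive diagonal.
#'
#' @param vol A [suv_volume()].
#' @param mask A [seg_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_suv_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  RNifti::writeNifti(nifti_from(vol), path, datatype = "double")
  invisible(path)
}

#' @rdname write_suv_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  RNifti::writeNifti(nifti_from(mask), path, datatype = "uint8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
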