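#' SUV volume and segmentation mask containers
#'
#' Lightweight containers for a 3D PET image expressed in standardized
#' uptake values (SUV, dimensionless) and for a binary lesion segmentation
#' on the same voxel lattice. Geometry follows the voxel-centre convention:
#' the world coordinate (mm) of the voxel with 0-based index `(i, j, k)` is
#' `origin + c(i, j, k) * spacing`.
#'
#' @param values A 3D numeric array. For `suv_volume()` all values must be
#'   finite and non-negative; for `seg_mask()` values must be 0/1.
#' @param spacing Numeric length-3 vector of positive voxel edge lengths in
#'   mm, one per array axis.
#' @param origin Numeric length-3 vector, the world position (mm) of the
#'   centre of voxel index `(0, 0, 0)`.
#' @param patient_id Character scalar identifying the scan.
#' @param reader_id Character scalar identifying who produced the
#'   segmentation (e.g. `"A"`, `"B"`, `"truth"`).
#'
#' @return An object of class `suv_volume` or `seg_mask`: a list with
#'   elements `values`, `spacing`, `origin` and the identifiers.
#' @examples
#' vol <- suv_volume(array(1, dim = c(4, 4, 4)), spacing = c(2, 2, 3))
#' msk <- seg_mask(array(0L, dim = c(4, 4, 4)), spacing = c(2, 2, 3))
#' check_grid_compatible(vol, msk)
#' @export
suv_volume <- function(values, spacing, origin = c(0, 0, 0),
                       patient_id = "patient") {
  check_geometry(values, spacing, origin)
  if (anyNA(values) || !all(is.finite(values))) {
    abort("SUV volume contains non-finite values.")
  }
  if (any(values < 0)) {
    abort("SUV volume contains negative values; SUV must be >= 0.")
  }
  structure(
    list(patient_id = as.character(patient_id), values = values,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "suv_volume"
  )
}

#' @rdname suv_volume
#' @export
seg_mask <- function(values, spacing, origin = c(0, 0, 0),
                     patient_id = "patient", reader_id = "reader") {
  check_geometry(values, spacing, origin)
  if (anyNA(values) || !all(values %in% c(0, 1))) {
    abort("Segmentation mask values must all be 0 or 1.")
  }
  storage.mode(values) <- "integer"
  structure(
    list(patient_id = as.character(patient_id),
         reader_id = as.character(reader_id), values = values,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "seg_mask"
  )
}

check_geometry <- function(values, spacing, origin) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("expected 3D volume: `values` must be a 3-dimensional array.")
  }
  if (any(dim(values) < 1L)) abort("every array dimension must be >= 1.")
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive voxel sizes in mm.")
  }
  if (length(origin) != 3L || anyNA(origin)) {
    abort("`origin` must be a numeric length-3 vector (mm).")
  }
  invisible(TRUE)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> patient %s: %s voxels, spacing %s mm\n",
              x$patient_id, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> patient %s, reader %s: %s voxels, %d foreground\n",
              x$patient_id, x$reader_id,
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Test whether a volume and a mask live on the same voxel lattice
#'
#' A pure predicate: `TRUE` iff the array shapes are identical, the voxel
#' spacings agree within `spacing_tol` mm on every axis and the origins
#' agree within `origin_tol` mm. Symmetric in its two arguments.
#'
#' @param vol,mask Objects with `values`, `spacing` and `origin` elements
#'   (a [suv_volume()] and a [seg_mask()], in either order).
#' @param spacing_tol,origin_tol Absolute per-axis tolerances in mm.
#' @return `TRUE` or `FALSE`.
#' @examples
#' v <- suv_volume(array(0, dim = c(4, 4, 4)), spacing = c(2, 2, 3))
#' m <- seg_mask(array(0L, dim = c(4, 4, 5)), spacing = c(2, 2, 3))
#' check_grid_compatible(v, m) # FALSE: shapes differ
#' @export
check_grid_compatible <- function(vol, mask, spacing_tol = 1e-3,
                                  origin_tol = 1e-2) {
  identical(dim(vol$values), dim(mask$values)) &&
    all(abs(vol$spacing - mask$spacing) <= spacing_tol) &&
    all(abs(vol$origin - mask$origin) <= origin_tol)
}

stop_unless_compatible <- function(vol, mask) {
  if (!check_grid_compatible(vol, mask)) {
    abort(sprintf(
      "volume and mask for patient '%s' are not grid-compatible (shape %s vs %s).",
      vol$patient_id, paste(dim(vol$values), collapse = "x"),
      paste(dim(mask$values), collapse = "x")))
  }
  invisible(TRUE)
}
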