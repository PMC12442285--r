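# Lesion extraction and the three patient-level biomarkers.
#
# A "lesion" is a maximal connected component of mask foreground under a
# configurable 3D neighbourhood (6 = faces, 18 = faces+edges, 26 =
# faces+edges+corners; default 26, the most inclusive standard choice for
# blobby PET uptake). All unit conversions are fixed here: voxel volume
# mm^3 -> cm^3 via /1000, centroid distances mm -> cm via /10.

connectivity_offsets <- function(connectivity, half = TRUE) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.")
  }
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- switch(as.character(connectivity),
              "6" = g[rowSums(abs(g)) == 1L, , drop = FALSE],
              "18" = g[rowSums(abs(g)) <= 2L, , drop = FALSE],
              "26" = g)
  if (half) {
    keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
    g <- g[keep, , drop = FALSE]
  }
  unname(g)
}

#' Partition mask foreground into connected lesions
#'
#' Labels the foreground of a binary mask into maximal connected components
#' under the chosen 3D connectivity. Components are returned in a
#' deterministic order (by lexicographically smallest member voxel), each as
#' a matrix of 1-based voxel indices sorted lexicographically.
#'
#' @param mask A [seg_mask()] or a 3D array of 0/1 values.
#' @param connectivity 6, 18 or 26 (default): which voxel neighbours belong
#'   to the same lesion.
#' @return A list of integer matrices with columns `i, j, k`; empty list for
#'   an empty mask.
#' @examples
#' m <- array(0L, dim = c(3, 3, 3)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
#' length(label_lesions(m, connectivity = 26)) # corner contact: one lesion
#' length(label_lesions(m, connectivity = 6))  # faces only: two lesions
#' @export
label_lesions <- function(mask, connectivity = 26) {
  vals <- if (inherits(mask, "seg_mask")) mask$values else mask
  if (!is.array(vals) || length(dim(vals)) != 3L) {
    abort("`mask` must be a seg_mask or a 3D array.")
  }
  if (!all(vals %in% c(0, 1))) abort("`mask` must be binary (0/1).")
  dims <- dim(vals)
  fg <- which(vals != 0)
  if (length(fg) == 0L) return(list())
  coords <- arrayInd(fg, dims)
  offs <- connectivity_offsets(connectivity, half = TRUE)

  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
      nb[, 2] >= 1L & nb[, 2] <= dims[2] &
      nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + dims[1] * ((nb[ok, 2] - 1L) + dims[2] * (nb[ok, 3] - 1L))
    j <- match(nb_lin, fg)
    hit <- !is.na(j)
    if (any(hit)) edges[[r]] <- cbind(which(ok)[hit], j[hit])
  }
  edges <- do.call(rbind, edges)

  n <- length(fg)
  if (is.null(edges)) {
    memb <- seq_len(n)
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
  }

  # order components by their lexicographically smallest member voxel
  lex <- order(coords[, 1], coords[, 2], coords[, 3])
  comp_ids <- unique(memb[lex])
  out <- vector("list", length(comp_ids))
  for (pos in seq_along(comp_ids)) {
    cm <- coords[memb == comp_ids[pos], , drop = FALSE]
    cm <- cm[order(cm[, 1], cm[, 2], cm[, 3]), , drop = FALSE]
    colnames(cm) <- c("i", "j", "k")
    out[[pos]] <- cm
  }
  out
}

#' Per-lesion statistics for one connected component
#'
#' Computes the lesion volume (cm^3), the arithmetic mean SUV over the
#' component's voxels, TLG = SUVmean x volume, and the unweighted geometric
#' centroid of the voxel-centre world coordinates (mm).
#'
#' @param component An integer matrix of 1-based voxel indices (columns
#'   `i, j, k`), e.g. one element of [label_lesions()].
#' @param vol The paired [suv_volume()].
#' @return A one-row tibble: `n_voxels`, `volume_cm3`, `suv_mean`, `tlg`,
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`.
#' @export
lesion_from_component <- function(component, vol) {
  component <- as.matrix(component)
  if (nrow(component) == 0L) abort("lesion component is empty.")
  dims <- dim(vol$values)
  if (any(component < 1L) ||
      any(component[, 1] > dims[1]) || any(component[, 2] > dims[2]) ||
      any(component[, 3] > dims[3])) {
    abort("lesion component references voxel indices outside the volume.")
  }
  lin <- component[, 1] + dims[1] * ((component[, 2] - 1L) + dims[2] * (component[, 3] - 1L))
  volume_cm3 <- nrow(component) * prod(vol$spacing) / 1000
  suv_mean <- mean(vol$values[lin])
  centroid <- vol$origin + (colMeans(component) - 1) * vol$spacing
  tibble(n_voxels = nrow(component), volume_cm3 = volume_cm3,
         suv_mean = suv_mean, tlg = suv_mean * volume_cm3,
         centroid_x_mm = centroid[1], centroid_y_mm = centroid[2],
         centroid_z_mm = centroid[3])
}

#' Tabulate all lesions of one reading
#'
#' Extracts connected lesions from the mask and returns their per-lesion
#' statistics as one tidy table.
#'
#' @inheritParams lesion_from_component
#' @param mask A [seg_mask()] grid-compatible with `vol`.
#' @param connectivity Passed to [label_lesions()].
#' @return A tibble with one row per lesion (`lesion_id` in deterministic
#'   label order) and the columns of [lesion_from_component()].
#' @export
lesion_table <- function(vol, mask, connectivity = 26) {
  stop_unless_compatible(vol, mask)
  comps <- label_lesions(mask, connectivity)
  if (length(comps) == 0L) {
    return(tibble(lesion_id = integer(), n_voxels = integer(),
                  volume_cm3 = numeric(), suv_mean = numeric(),
                  tlg = numeric(), centroid_x_mm = numeric(),
                  centroid_y_mm = numeric(), centroid_z_mm = numeric()))
  }
  dplyr::bind_rows(purrr::map(comps, lesion_from_component, vol = vol),
                   .id = "lesion_id") |>
    dplyr::mutate(lesion_id = as.integer(.data$lesion_id))
}

#' Lesion dissemination distance Dmax
#'
#' The Euclidean distance (cm) between the centroids of the two most widely
#' separated lesions; defined as 0 when fewer than two lesions are present.
#'
#' @param lesions A lesion table as from [lesion_table()] (columns
#'   `centroid_x_mm`, `centroid_y_mm`, `centroid_z_mm`), or a numeric
#'   matrix of centroid coordinates in mm (one row per lesion).
#' @return A non-negative scalar in cm.
#' @examples
#' compute_dmax(rbind(c(0, 0, 0), c(30, 40, 0))) # 3-4-5 triangle: 5 cm
#' @export
compute_dmax <- function(lesions) {
  cent <- if (is.matrix(lesions)) lesions else
    as.matrix(lesions[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")])
  if (nrow(cent) < 2L) return(0)
  max(dist(cent)) / 10
}

#' Exclude small lesions
#'
#' Drops lesions strictly smaller than `min_volume_cm3`; a lesion of exactly
#' the threshold volume is retained. Row order is preserved.
#'
#' @param lesions A lesion table with a `volume_cm3` column.
#' @param min_volume_cm3 Non-negative volume threshold in cm^3 (default 3).
#' @return The filtered lesion table.
#' @export
apply_volume_filter <- function(lesions, min_volume_cm3 = 3) {
  if (min_volume_cm3 < 0) abort("`min_volume_cm3` must be >= 0.")
  lesions[lesions$volume_cm3 >= min_volume_cm3, , drop = FALSE]
}

filter_label_for <- function(min_volume_cm3) {
  if (is.null(min_volume_cm3)) "all" else
    paste0("ge", format(min_volume_cm3, trim = TRUE, scientific = FALSE), "cm3")
}

#' Patient-level biomarkers MTV, TLG and Dmax for one reading
#'
#' MTV (cm^3) is the total volume of all voxels labelled as lesion; TLG is
#' the sum over lesions of SUVmean x lesion volume; Dmax (cm) is the
#' centroid distance between the two most widely separated lesions (0 when
#' fewer than two). When `min_volume_cm3` is given, lesions strictly below
#' the threshold are excluded before all three metrics are computed and the
#' row is labelled accordingly (e.g. `"ge3cm3"`); otherwise the label is
#' `"all"`.
#'
#' @inheritParams lesion_table
#' @param min_volume_cm3 Optional small-lesion exclusion threshold in cm^3;
#'   `NULL` (default) keeps every lesion.
#' @return A one-row tibble: `patient_id`, `reader_id`, `filter_label`,
#'   `mtv_cm3`, `tlg`, `dmax_cm`, `n_lesions`.
#' @examples
#' vol <- suv_volume(array(4, dim = c(10, 10, 10)), spacing = c(1, 1, 1))
#' m <- array(0L, dim = c(10, 10, 10)); m[1:10, 1:10, 1:10] <- 1L
#' compute_patient_metrics(vol, seg_mask(m, spacing = c(1, 1, 1)))
#' @export
compute_patient_metrics <- function(vol, mask, connectivity = 26,
                                    min_volume_cm3 = NULL) {
  lesions <- lesion_table(vol, mask, connectivity)
  if (!is.null(min_volume_cm3)) {
    lesions <- apply_volume_filter(lesions, min_volume_cm3)
  }
  tibble(
    patient_id = vol$patient_id,
    reader_id = mask$reader_id,
    filter_label = filter_label_for(min_volume_cm3),
    mtv_cm3 = sum(lesions$volume_cm3),
    tlg = sum(lesions$tlg),
    dmax_cm = compute_dmax(lesions),
    n_lesions = nrow(lesions)
  )
}
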