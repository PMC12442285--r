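# Synthetic two-reader phantom cohorts.
#
# Each patient is a set of non-touching spheres with a radially decreasing
# SUV profile on a uniform background. Reader disagreement is modelled by
# the two mechanisms that drive inter-reader variability of these
# biomarkers: (1) per-lesion boundary jitter -- each reader dilates or
# erodes each lesion by a random signed margin -- and (2) inconsistent
# inclusion of small lesions -- each reader independently omits a lesion
# below a volume threshold with a fixed probability. Randomness is split
# into named substreams (truth, reader A, reader B) per patient so a
# cohort is fully reproducible from one master seed.

#' Configuration of a synthetic two-reader phantom cohort
#'
#' Defaults describe a cohort of 117 patients on a whole-body-like PET
#' grid (80 x 80 x 112 voxels at 4 mm isotropic), with on average 6
#' spherical lesions per patient (Poisson, floored at 1), radii uniform in
#' 5-30 mm, SUV peaks uniform in 5-25 on a background of 1, per-lesion
#' boundary jitter up to +/-6 mm, and a 50% chance per reader of omitting
#' any lesion smaller than 3 cm^3.
#'
#' @param n_patients Number of phantom patients.
#' @param seed Master seed; every random draw derives from it.
#' @param grid_shape Integer length-3 array dimensions.
#' @param spacing_mm Positive length-3 voxel size in mm.
#' @param lesion_count_mean Poisson mean lesion count (minimum 1 enforced).
#' @param radius_range_mm Uniform range for sphere radii (mm).
#' @param suv_peak_range Uniform range for the central SUV of each lesion;
#'   the lower bound must exceed `background_suv`.
#' @param background_suv Background SUV outside lesions.
#' @param boundary_jitter_mm Per-lesion, per-reader boundary
#'   dilation/erosion margin is drawn uniformly from
#'   `[-boundary_jitter_mm, +boundary_jitter_mm]`.
#' @param small_lesion_omit_prob Probability that a reader omits a lesion
#'   whose true volume is below `omit_volume_threshold_cm3`.
#' @param omit_volume_threshold_cm3 Volume threshold (cm^3) under which a
#'   lesion is eligible for omission.
#' @return A validated object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 117, seed = 1,
                           grid_shape = c(80, 80, 112),
                           spacing_mm = c(4, 4, 4),
                           lesion_count_mean = 6,
                           radius_range_mm = c(5, 30),
                           suv_peak_range = c(5, 25),
                           background_suv = 1,
                           boundary_jitter_mm = 6,
                           small_lesion_omit_prob = 0.5,
                           omit_volume_threshold_cm3 = 3) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              lesion_count_mean = as.numeric(lesion_count_mean),
              radius_range_mm = as.numeric(radius_range_mm),
              suv_peak_range = as.numeric(suv_peak_range),
              background_suv = as.numeric(background_suv),
              boundary_jitter_mm = as.numeric(boundary_jitter_mm),
              small_lesion_omit_prob = as.numeric(small_lesion_omit_prob),
              omit_volume_threshold_cm3 = as.numeric(omit_volume_threshold_cm3))
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1L) abort("`n_patients` must be >= 1.")
    if (length(grid_shape) != 3L || any(grid_shape < 2L)) {
      abort("`grid_shape` must be 3 integers >= 2.")
    }
    if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
      abort("`spacing_mm` must be 3 positive values.")
    }
    if (lesion_count_mean <= 0) abort("`lesion_count_mean` must be > 0.")
    for (nm in c("radius_range_mm", "suv_peak_range")) {
      rg <- cfg[[nm]]
      if (length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2]) {
        abort(sprintf("`%s` must be an ordered pair of positive values.", nm))
      }
    }
    if (suv_peak_range[1] <= background_suv) {
      abort("`suv_peak_range` lower bound must exceed `background_suv`.")
    }
    if (background_suv < 0) abort("`background_suv` must be >= 0.")
    if (boundary_jitter_mm < 0) abort("`boundary_jitter_mm` must be >= 0.")
    if (small_lesion_omit_prob < 0 || small_lesion_omit_prob > 1) {
      abort("`small_lesion_omit_prob` must be a probability in [0, 1].")
    }
    if (omit_volume_threshold_cm3 <= 0) {
      abort("`omit_volume_threshold_cm3` must be > 0.")
    }
    extent <- (grid_shape - 1) * spacing_mm
    if (any(extent < 2 * (radius_range_mm[2] + boundary_jitter_mm))) {
      abort("grid is too small to contain the largest lesion radius plus jitter.")
    }
  })
  structure(cfg, class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config> %d patients, grid %s @ %s mm, seed %d\n",
    x$n_patients, paste(x$grid_shape, collapse = "x"),
    paste(format(x$spacing_mm), collapse = "x"), x$seed))
  cat(sprintf(
    "  lesions ~ max(1, Pois(%.3g)), radius U(%g, %g) mm, SUV peak U(%g, %g) on background %g\n",
    x$lesion_count_mean, x$radius_range_mm[1], x$radius_range_mm[2],
    x$suv_peak_range[1], x$suv_peak_range[2], x$background_suv))
  cat(sprintf(
    "  reader model: boundary jitter +/-%g mm; omit P=%g for lesions < %g cm^3\n",
    x$boundary_jitter_mm, x$small_lesion_omit_prob,
    x$omit_volume_threshold_cm3))
  invisible(x)
}

# one sub-seed per patient and named stream, derived from the master seed
phantom_seeds <- function(config) {
  set.seed(config$seed)
  m <- matrix(sample.int(2147483646L, config$n_patients * 3L),
              nrow = config$n_patients)
  colnames(m) <- c("truth", "reader_a", "reader_b")
  m
}

phantom_patient_ids <- function(config) {
  sprintf("phantom%03d", seq_len(config$n_patients))
}

#' Draw ground-truth lesion parameters for a phantom cohort
#'
#' Per patient the lesion count is `max(1, Poisson(lesion_count_mean))`;
#' radii and SUV peaks are uniform in their configured ranges; centres are
#' uniform inside the grid with full-sphere containment and pairwise
#' centre separation of at least the sum of radii plus two voxels, so that
#' true lesions never touch and the true lesion count is unambiguous under
#' any connectivity. Fully reproducible from `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return A tibble with one row per lesion: `patient_id`, `lesion_id`,
#'   `center_x_mm`, `center_y_mm`, `center_z_mm`, `radius_mm`, `suv_peak`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  seeds <- phantom_seeds(config)
  ids <- phantom_patient_ids(config)
  extent <- (config$grid_shape - 1) * config$spacing_mm
  sep_pad <- 2 * max(config$spacing_mm)
  purrr::map(seq_len(config$n_patients), function(i) {
    set.seed(seeds[i, "truth"])
    count <- max(1L, rpois(1L, config$lesion_count_mean))
    radii <- runif(count, config$radius_range_mm[1], config$radius_range_mm[2])
    peaks <- runif(count, config$suv_peak_range[1], config$suv_peak_range[2])
    centers <- matrix(NA_real_, count, 3L)
    for (l in seq_len(count)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        cand <- runif(3L, radii[l], extent - radii[l])
        prev <- seq_len(l - 1L)
        if (l == 1L || all(sqrt(colSums((t(centers[prev, , drop = FALSE]) - cand)^2)) >=
                           radii[l] + radii[prev] + sep_pad)) {
          centers[l, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place lesion %d of %d for patient %s: the phantom configuration is too congested (grid %s mm, radii up to %g mm).",
          l, count, ids[i], paste(round(extent), collapse = "x"),
          config$radius_range_mm[2]))
      }
    }
    tibble(patient_id = ids[i], lesion_id = seq_len(count),
           center_x_mm = centers[, 1], center_y_mm = centers[, 2],
           center_z_mm = centers[, 3], radius_mm = radii, suv_peak = peaks)
  }) |> dplyr::bind_rows()
}

#' Rasterize one phantom patient onto the voxel grid
#'
#' A voxel is lesion foreground iff its centre lies within some lesion
#' sphere. The SUV image equals `background_suv` outside lesions; inside
#' lesion i it follows the parabolic radial profile
#' `background + (peak_i - background) * (1 - (d/r_i)^2)`, which peaks at
#' the sphere centre and falls to the background at the boundary.
#'
#' @param truth The rows of [generate_truth()] belonging to one patient.
#' @param config The [phantom_config()].
#' @return A list with elements `suv` (a [suv_volume()]) and `mask` (the
#'   true [seg_mask()], reader id `"truth"`).
#' @export
rasterize_patient <- function(truth, config) {
  stopifnot(inherits(config, "phantom_config"))
  pid <- unique(truth$patient_id)
  if (length(pid) != 1L) abort("`truth` must contain exactly one patient.")
  shape <- config$grid_shape
  sp <- config$spacing_mm
  bg <- config$background_suv
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * sp[a])
  suv <- array(bg, dim = shape)
  msk <- array(0L, dim = shape)
  for (l in seq_len(nrow(truth))) {
    ctr <- c(truth$center_x_mm[l], truth$center_y_mm[l], truth$center_z_mm[l])
    r <- truth$radius_mm[l]
    lo <- pmax(1L, floor((ctr - r) / sp) + 1L)
    hi <- pmin(shape, ceiling((ctr + r) / sp) + 1L)
    d2 <- outer(outer((ax[[1]][lo[1]:hi[1]] - ctr[1])^2,
                      (ax[[2]][lo[2]:hi[2]] - ctr[2])^2, "+"),
                (ax[[3]][lo[3]:hi[3]] - ctr[3])^2, "+")
    inside <- d2 <= r^2
    sub_m <- msk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub_m[inside] <- 1L
    msk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub_m
    sub_s <- suv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub_s[inside] <- bg + (truth$suv_peak[l] - bg) * (1 - d2[inside] / r^2)
    suv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub_s
  }
  list(suv = suv_volume(suv, sp, patient_id = pid),
       mask = seg_mask(msk, sp, patient_id = pid, reader_id = "truth"))
}

# --- discrete morphology -------------------------------------------------

# digital-ball structuring element: integer offsets whose physical length
# does not exceed |margin|; margins below the smallest voxel step therefore
# round toward zero (identity)
se_offsets <- function(margin_mm, spacing) {
  m <- abs(margin_mm)
  r_vox <- floor(m / spacing + 1e-9)
  if (all(r_vox == 0)) return(matrix(0L, 1L, 3L))
  g <- as.matrix(expand.grid(di = -r_vox[1]:r_vox[1],
                             dj = -r_vox[2]:r_vox[2],
                             dk = -r_vox[3]:r_vox[3]))
  g[rowSums(sweep(g, 2L, spacing, "*")^2) <= m^2 + 1e-9, , drop = FALSE]
}

voxel_key <- function(coords, dims) {
  coords[, 1] + as.numeric(dims[1]) *
    ((coords[, 2] - 1) + as.numeric(dims[2]) * (coords[, 3] - 1))
}

dilate_component <- function(coords, offsets, dims) {
  parts <- lapply(seq_len(nrow(offsets)), function(r) {
    nb <- sweep(coords, 2L, offsets[r, ], "+")
    nb[nb[, 1] >= 1L & nb[, 1] <= dims[1] &
         nb[, 2] >= 1L & nb[, 2] <= dims[2] &
         nb[, 3] >= 1L & nb[, 3] <= dims[3], , drop = FALSE]
  })
  all_c <- do.call(rbind, parts)
  all_c[!duplicated(voxel_key(all_c, dims)), , drop = FALSE]
}

erode_component <- function(coords, offsets, dims) {
  keys <- voxel_key(coords, dims)
  keep <- rep(TRUE, nrow(coords))
  for (r in seq_len(nrow(offsets))) {
    if (all(offsets[r, ] == 0L)) next
    nb <- sweep(coords, 2L, offsets[r, ], "+")
    inb <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
      nb[, 2] >= 1L & nb[, 2] <= dims[2] &
      nb[, 3] >= 1L & nb[, 3] <= dims[3]
    member <- inb
    member[inb] <- voxel_key(nb[inb, , drop = FALSE], dims) %in% keys
    keep <- keep & member
  }
  coords[keep, , drop = FALSE]
}

#' Simulate one reader's segmentation of a true mask
#'
#' Applies the two-part reader model independently per true lesion: with
#' probability `small_lesion_omit_prob` a lesion smaller than
#' `omit_volume_threshold_cm3` is omitted entirely; every retained lesion
#' is dilated (positive margin) or eroded (negative margin) by a signed
#' margin drawn uniformly from `[-boundary_jitter_mm, boundary_jitter_mm]`,
#' realised as discrete morphology with a digital-ball structuring element
#' scaled by the voxel spacing (margins below one voxel step round toward
#' zero, i.e. leave the lesion unchanged). With zero jitter and zero omit
#' probability the output equals the input exactly.
#'
#' @param true_mask The ground-truth [seg_mask()].
#' @param config The [phantom_config()] supplying the perturbation
#'   parameters.
#' @param reader_id Identifier stored in the returned mask.
#' @param seed Optional seed for this reading's random substream; when
#'   `NULL` the current RNG state is used.
#' @param systematic_margin_mm A constant added to every drawn margin,
#'   modelling a reader who systematically over- (positive) or
#'   under-segments (negative).
#' @return A [seg_mask()] on the same grid.
#' @export
perturb_reading <- function(true_mask, config, reader_id = "reader",
                            seed = NULL, systematic_margin_mm = 0) {
  stopifnot(inherits(true_mask, "seg_mask"), inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(true_mask$values)
  sp <- true_mask$spacing
  vox_cm3 <- prod(sp) / 1000
  comps <- label_lesions(true_mask, connectivity = 26)
  k <- length(comps)
  u_omit <- runif(k)
  margins <- runif(k, -config$boundary_jitter_mm, config$boundary_jitter_mm) +
    systematic_margin_mm
  out <- array(0L, dim = dims)
  for (l in seq_len(k)) {
    comp <- comps[[l]]
    small <- nrow(comp) * vox_cm3 < config$omit_volume_threshold_cm3
    if (small && u_omit[l] < config$small_lesion_omit_prob) next
    offs <- se_offsets(margins[l], sp)
    if (nrow(offs) > 1L) {
      comp <- if (margins[l] > 0) dilate_component(comp, offs, dims)
      else erode_component(comp, offs, dims)
    }
    if (nrow(comp)) out[voxel_key(comp, dims)] <- 1L
  }
  seg_mask(out, sp, true_mask$origin, patient_id = true_mask$patient_id,
           reader_id = reader_id)
}

simulate_patient <- function(config, i, seeds, truth_all) {
  truth <- truth_all[truth_all$patient_id == phantom_patient_ids(config)[i], ]
  ras <- rasterize_patient(truth, config)
  list(
    truth = truth,
    suv = ras$suv,
    mask_truth = ras$mask,
    mask_a = perturb_reading(ras$mask, config, reader_id = "A",
                             seed = seeds[i, "reader_a"]),
    mask_b = perturb_reading(ras$mask, config, reader_id = "B",
                             seed = seeds[i, "reader_b"])
  )
}

patient_metric_rows <- function(suv, masks, connectivity, min_volume_cm3) {
  purrr::map(masks, function(m) {
    dplyr::bind_rows(
      compute_patient_metrics(suv, m, connectivity),
      compute_patient_metrics(suv, m, connectivity,
                              min_volume_cm3 = min_volume_cm3))
  }) |> dplyr::bind_rows()
}

#' Simulate a phantom cohort directly to a metrics table
#'
#' Runs the whole in-memory chain -- truth, rasterization, two perturbed
#' readings, lesion labelling and biomarker computation -- without touching
#' the filesystem, and returns the per-patient metrics for both readers
#' and both filter variants (`"all"` and the small-lesion exclusion).
#'
#' @param config A [phantom_config()].
#' @param connectivity Lesion connectivity passed to the metrics stage.
#' @param min_volume_cm3 Small-lesion exclusion threshold for the filtered
#'   variant.
#' @return A metrics tibble with the columns of [read_metrics_table()],
#'   ready for [agreement_study()].
#' @export
simulate_metrics <- function(config, connectivity = 26, min_volume_cm3 = 3) {
  stopifnot(inherits(config, "phantom_config"))
  seeds <- phantom_seeds(config)
  truth_all <- generate_truth(config)
  purrr::map(seq_len(config$n_patients), function(i) {
    p <- simulate_patient(config, i, seeds, truth_all)
    patient_metric_rows(p$suv, list(p$mask_a, p$mask_b),
                        connectivity, min_volume_cm3)
  }) |> dplyr::bind_rows()
}

#' Write a phantom cohort to disk
#'
#' Emits, per patient, the SUV volume and the two reader masks as NIfTI-1
#' files, a `cohort.csv` manifest of file paths, and a `manifest.json`
#' ground-truth manifest holding the analytic lesion parameters and the
#' expected per-reader metrics computed from the realized (perturbed)
#' masks -- the same numbers the metrics pipeline must reproduce when it
#' reads the files back.
#'
#' @inheritParams simulate_metrics
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `manifest` (JSON path),
#'   `cohort_csv` (path manifest) and `files` (tibble of per-patient
#'   paths).
#' @export
generate_cohort <- function(config, dir, connectivity = 26,
                            min_volume_cm3 = 3) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'.", dir))
  seeds <- phantom_seeds(config)
  truth_all <- generate_truth(config)
  ids <- phantom_patient_ids(config)

  patients <- vector("list", config$n_patients)
  files <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    p <- simulate_patient(config, i, seeds, truth_all)
    fn <- c(suv = sprintf("%s_suv.nii.gz", ids[i]),
            mask_a = sprintf("%s_mask_A.nii.gz", ids[i]),
            mask_b = sprintf("%s_mask_B.nii.gz", ids[i]))
    write_suv_volume(p$suv, file.path(dir, fn[["suv"]]))
    write_mask(p$mask_a, file.path(dir, fn[["mask_a"]]))
    write_mask(p$mask_b, file.path(dir, fn[["mask_b"]]))
    expected <- patient_metric_rows(p$suv, list(p$mask_a, p$mask_b),
                                    connectivity, min_volume_cm3)
    patients[[i]] <- list(patient_id = ids[i], files = as.list(fn),
                          lesions = p$truth,
                          expected_metrics = expected)
    files[[i]] <- tibble(patient_id = ids[i], suv_path = fn[["suv"]],
                         mask_a_path = fn[["mask_a"]],
                         mask_b_path = fn[["mask_b"]])
  }
  files <- dplyr::bind_rows(files)
  cohort_csv <- file.path(dir, "cohort.csv")
  readr::write_csv(files, cohort_csv)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = unclass(config), connectivity = connectivity,
         min_volume_cm3 = min_volume_cm3, patients = patients),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, manifest = manifest_path,
                 cohort_csv = cohort_csv, files = files))
}
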