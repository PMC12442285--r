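test_that("phantom configs are validated field by field", {
  expect_s3_class(phantom_config(), "phantom_config")
  expect_error(small_config(small_lesion_omit_prob = 1.5),
               "small_lesion_omit_prob")
  expect_error(small_config(radius_range_mm = c(10, 5)), "radius_range_mm")
  expect_error(small_config(suv_peak_range = c(0.5, 2), background_suv = 1),
               "background_suv")
  expect_error(small_config(grid_shape = c(6, 6, 6), radius_range_mm = c(5, 30)),
               "too small")
})

test_that("the same seed reproduces a cohort exactly", {
  cfg <- small_config(seed = 31, n_patients = 4)
  expect_identical(generate_truth(cfg), generate_truth(cfg))
  expect_identical(simulate_metrics(cfg), simulate_metrics(cfg))
  # different seeds give different cohorts
  expect_false(identical(generate_truth(cfg),
                         generate_truth(small_config(seed = 32, n_patients = 4))))
})

test_that("truth respects the lesion-count floor, ranges and separation", {
  # a tiny Poisson mean still yields at least one lesion everywhere
  cfg1 <- small_config(seed = 8, n_patients = 12, lesion_count_mean = 0.01)
  counts <- dplyr::count(generate_truth(cfg1), patient_id)
  expect_true(all(counts$n >= 1))

  # distributional check on many radii: range respected, mean within 3 SE
  cfg2 <- phantom_config(
    n_patients = 400, seed = 19, grid_shape = c(41, 41, 41),
    spacing_mm = c(4, 4, 4), lesion_count_mean = 25,
    radius_range_mm = c(5, 10), suv_peak_range = c(5, 25),
    boundary_jitter_mm = 0)
  radii <- generate_truth(cfg2)$radius_mm
  expect_gte(length(radii), 8000)
  expect_gte(min(radii), 5)
  expect_lte(max(radii), 10)
  se <- (10 - 5) / sqrt(12) / sqrt(length(radii))
  expect_lt(abs(mean(radii) - 7.5), 3 * se)

  # pairwise separation >= sum of radii + 2 voxels within every patient
  truth <- generate_truth(small_config(seed = 4, n_patients = 5))
  for (pid in unique(truth$patient_id)) {
    tt <- truth[truth$patient_id == pid, ]
    if (nrow(tt) < 2) next
    cent <- as.matrix(tt[, c("center_x_mm", "center_y_mm", "center_z_mm")])
    for (i in seq_len(nrow(tt) - 1)) {
      for (j in (i + 1):nrow(tt)) {
        expect_gte(sqrt(sum((cent[i, ] - cent[j, ])^2)),
                   tt$radius_mm[i] + tt$radius_mm[j] + 8)
      }
    }
  }

  # congested configuration fails with an informative error
  cfg_bad <- phantom_config(
    n_patients = 1, seed = 1, grid_shape = c(16, 16, 16),
    spacing_mm = c(4, 4, 4), lesion_count_mean = 8,
    radius_range_mm = c(25, 28), suv_peak_range = c(5, 25),
    boundary_jitter_mm = 0)
  expect_error(generate_truth(cfg_bad), "congested")
})

test_that("rasterization follows the voxel-centre-in-sphere rule", {
  cfg <- small_config(n_patients = 1)
  # sub-voxel sphere centred on a voxel centre -> exactly one voxel
  tiny <- single_sphere_truth(c(40, 40, 60), radius_mm = 0.4 * 4)
  ras <- rasterize_patient(tiny, cfg)
  expect_equal(sum(ras$mask$values), 1L)
  expect_equal(ras$mask$values[11, 11, 16], 1L) # index 0-based (10,10,15)

  # SUV peaks at the centre and is background outside
  expect_equal(ras$suv$values[11, 11, 16], 10)
  expect_equal(ras$suv$values[1, 1, 1], cfg$background_suv)

  # digitized sphere volume approximates (4/3) pi r^3, improving with
  # finer spacing
  vol_at <- function(spacing) {
    cfgs <- phantom_config(
      n_patients = 1, seed = 1,
      grid_shape = ceiling(60 / spacing) * c(1, 1, 1),
      spacing_mm = rep(spacing, 3), lesion_count_mean = 1,
      radius_range_mm = c(5, 12), suv_peak_range = c(5, 25),
      boundary_jitter_mm = 0)
    ras <- rasterize_patient(single_sphere_truth(c(25, 25, 25), 10), cfgs)
    sum(ras$mask$values) * spacing^3 / 1000
  }
  analytic <- 4 / 3 * pi * 10^3 / 1000
  err2 <- abs(vol_at(2) - analytic) / analytic
  err1 <- abs(vol_at(1) - analytic) / analytic
  err05 <- abs(vol_at(0.5) - analytic) / analytic
  expect_lt(err2, 0.15)
  expect_lt(err1, err2)
  expect_lt(err05, 0.05)

  # every rasterized true lesion is one connected component under 6- and
  # 26-connectivity, so the true lesion count is connectivity-independent
  truth <- generate_truth(small_config(seed = 9, n_patients = 3))
  for (pid in unique(truth$patient_id)) {
    tt <- truth[truth$patient_id == pid, ]
    ras <- rasterize_patient(tt, small_config(seed = 9, n_patients = 3))
    expect_length(label_lesions(ras$mask, 26), nrow(tt))
    expect_length(label_lesions(ras$mask, 6), nrow(tt))
  }
})

test_that("reader perturbation honours its identity and omission contracts", {
  cfg0 <- zero_perturbation_config(seed = 14, n_patients = 1)
  truth <- generate_truth(cfg0)
  ras <- rasterize_patient(truth, cfg0)
  same <- perturb_reading(ras$mask, cfg0, reader_id = "A", seed = 99)
  expect_identical(same$values, ras$mask$values)

  # omit probability 1 with every lesion under the threshold empties the mask
  cfg_small <- phantom_config(
    n_patients = 1, seed = 5, grid_shape = c(40, 40, 40),
    spacing_mm = c(2, 2, 2), lesion_count_mean = 4,
    radius_range_mm = c(3, 6), suv_peak_range = c(5, 25),
    boundary_jitter_mm = 0, small_lesion_omit_prob = 1,
    omit_volume_threshold_cm3 = 3)
  truth2 <- generate_truth(cfg_small)
  ras2 <- rasterize_patient(truth2, cfg_small)
  expect_gt(sum(ras2$mask$values), 0)
  gone <- perturb_reading(ras2$mask, cfg_small, seed = 1)
  expect_equal(sum(gone$values), 0L)

  # lesions at/above the threshold are never omitted
  cfg_keep <- phantom_config(
    n_patients = 1, seed = 5, grid_shape = c(46, 46, 46),
    spacing_mm = c(2, 2, 2), lesion_count_mean = 3,
    radius_range_mm = c(12, 16), suv_peak_range = c(5, 25),
    boundary_jitter_mm = 0, small_lesion_omit_prob = 1,
    omit_volume_threshold_cm3 = 3)
  truth3 <- generate_truth(cfg_keep)
  ras3 <- rasterize_patient(truth3, cfg_keep)
  kept <- perturb_reading(ras3$mask, cfg_keep, seed = 2)
  expect_identical(kept$values, ras3$mask$values)
})

test_that("omission frequency matches the configured probability", {
  cfg <- phantom_config(
    n_patients = 40, seed = 77, grid_shape = c(41, 41, 41),
    spacing_mm = c(4, 4, 4), lesion_count_mean = 12,
    radius_range_mm = c(5, 8), suv_peak_range = c(5, 25),
    boundary_jitter_mm = 0, small_lesion_omit_prob = 0.5,
    omit_volume_threshold_cm3 = 3)
  truth <- generate_truth(cfg)
  seeds_used <- 1000 + seq_len(cfg$n_patients)
  n_total <- 0
  n_omitted <- 0
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("phantom%03d", i)
    tt <- truth[truth$patient_id == pid, ]
    ras <- rasterize_patient(tt, cfg)
    # all lesions here are < 3 cm^3 (r <= 8 mm), so all are eligible
    pert <- perturb_reading(ras$mask, cfg, seed = seeds_used[i])
    n_total <- n_total + nrow(tt)
    n_omitted <- n_omitted + nrow(tt) - length(label_lesions(pert, 26))
  }
  expect_gte(n_total, 300)
  se <- sqrt(0.25 / n_total)
  expect_lt(abs(n_omitted / n_total - 0.5), 3 * se)
})

test_that("dilation and erosion margins change volume in the right direction", {
  cfg <- small_config(n_patients = 1, boundary_jitter_mm = 0,
                      small_lesion_omit_prob = 0)
  ras <- rasterize_patient(single_sphere_truth(c(60, 60, 80), 16), cfg)
  base <- sum(ras$mask$values)
  grow <- perturb_reading(ras$mask, cfg, seed = 1, systematic_margin_mm = 4)
  shrink <- perturb_reading(ras$mask, cfg, seed = 1, systematic_margin_mm = -4)
  sub <- perturb_reading(ras$mask, cfg, seed = 1, systematic_margin_mm = 3.9)
  expect_gt(sum(grow$values), base)
  expect_lt(sum(shrink$values), base)
  expect_equal(sum(sub$values), base) # margin below one voxel step: identity
})

test_that("a systematic reader-B dilation produces a negative MTV bias", {
  hits <- 0
  for (s in 1:20) {
    cfg <- small_config(seed = 100 + s, n_patients = 4,
                        boundary_jitter_mm = 0, small_lesion_omit_prob = 0)
    truth <- generate_truth(cfg)
    diffs <- purrr::map_dbl(unique(truth$patient_id), function(pid) {
      ras <- rasterize_patient(truth[truth$patient_id == pid, ], cfg)
      a <- perturb_reading(ras$mask, cfg, reader_id = "A", seed = 1)
      b <- perturb_reading(ras$mask, cfg, reader_id = "B", seed = 2,
                           systematic_margin_mm = 4)
      compute_patient_metrics(ras$suv, a)$mtv_cm3 -
        compute_patient_metrics(ras$suv, b)$mtv_cm3
    })
    if (mean(diffs) < 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("cohorts written to disk are self-consistent with their manifest", {
  cfg <- small_config(seed = 23, n_patients = 3)
  dir <- withr::local_tempdir()
  res <- generate_cohort(cfg, dir)
  expect_length(list.files(dir, pattern = "\\.nii\\.gz$"), 9L)
  expect_true(file.exists(res$manifest))
  expect_true(file.exists(res$cohort_csv))

  man <- jsonlite::read_json(res$manifest, simplifyVector = TRUE)
  for (i in seq_len(3)) {
    pid <- man$patients$patient_id[i]
    suv <- read_suv_volume(file.path(dir, man$patients$files$suv[i]),
                           patient_id = pid)
    for (rd in c("A", "B")) {
      msk <- read_mask(
        file.path(dir, man$patients$files[[paste0("mask_", tolower(rd))]][i]),
        reader_id = rd, patient_id = pid)
      got <- dplyr::bind_rows(
        compute_patient_metrics(suv, msk),
        compute_patient_metrics(suv, msk, min_volume_cm3 = 3))
      want <- man$patients$expected_metrics[[i]]
      want <- want[want$reader_id == rd, ]
      expect_equal(got$mtv_cm3, want$mtv_cm3, tolerance = 1e-6)
      expect_equal(got$tlg, want$tlg, tolerance = 1e-6)
      expect_equal(got$dmax_cm, want$dmax_cm, tolerance = 1e-6)
      expect_equal(got$n_lesions, as.integer(want$n_lesions))
    }
  }

  # regenerating with the same config yields an identical manifest and
  # identical voxel data
  dir2 <- withr::local_tempdir()
  generate_cohort(cfg, dir2)
  expect_identical(readLines(res$manifest),
                   readLines(file.path(dir2, "manifest.json")))
  v1 <- read_mask(file.path(dir, "phantom001_mask_A.nii.gz"))
  v2 <- read_mask(file.path(dir2, "phantom001_mask_A.nii.gz"))
  expect_identical(v1$values, v2$values)

  # zero-perturbation cohorts give byte-identical reader masks per patient
  dir3 <- withr::local_tempdir()
  generate_cohort(zero_perturbation_config(seed = 23, n_patients = 2), dir3)
  a <- read_mask(file.path(dir3, "phantom001_mask_A.nii.gz"))
  b <- read_mask(file.path(dir3, "phantom001_mask_B.nii.gz"))
  expect_identical(a$values, b$values)
})

test_that("default-scale cohorts land in a clinically plausible MTV range", {
  cfg <- phantom_config(n_patients = 20, seed = 6)
  m <- simulate_metrics(cfg)
  med_mtv <- median(m$mtv_cm3[m$filter_label == "all"])
  expect_gt(med_mtv, 100)
  expect_lt(med_mtv, 1000)
  # TLG exceeds MTV (SUV well above 1 inside lesions); Dmax spans tens of cm
  expect_gt(median(m$tlg[m$filter_label == "all"]), med_mtv)
  expect_gt(median(m$dmax_cm[m$filter_label == "all"]), 10)
})
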