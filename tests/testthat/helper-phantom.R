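# small phantom configurations used across tests; grids are deliberately
# modest so the whole suite stays fast

small_config <- function(seed = 1, n_patients = 6, ...) {
  args <- list(
    n_patients = n_patients, seed = seed,
    grid_shape = c(36, 36, 48), spacing_mm = c(4, 4, 4),
    lesion_count_mean = 4, radius_range_mm = c(5, 14),
    suv_peak_range = c(5, 20), background_suv = 1,
    boundary_jitter_mm = 5, small_lesion_omit_prob = 0.3,
    omit_volume_threshold_cm3 = 3)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

zero_perturbation_config <- function(seed = 1, n_patients = 8, ...) {
  small_config(seed = seed, n_patients = n_patients,
               boundary_jitter_mm = 0, small_lesion_omit_prob = 0, ...)
}

# truth table for a single hand-placed patient, for rasterization tests
single_sphere_truth <- function(center_mm, radius_mm, suv_peak = 10,
                                patient_id = "p1") {
  tibble::tibble(patient_id = patient_id, lesion_id = 1L,
                 center_x_mm = center_mm[1], center_y_mm = center_mm[2],
                 center_z_mm = center_mm[3], radius_mm = radius_mm,
                 suv_peak = suv_peak)
}
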