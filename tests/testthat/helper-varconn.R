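# Shared fixtures, built in code.

# Small, fast study specification for unit tests.
tiny_spec <- function(seed = 1, ...) {
  args <- list(
    grid_shape = c(8, 8, 6), n_parcels = 5,
    n_blind_A = 3, n_sighted_A = 3, n_blind_B = 3, n_sighted_B = 3,
    n_vols_by_cohort = c(A = 60, B = 80),
    region_effects = default_region_effects(5),
    rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_spec, args)
}

# Deterministic-signal specification: no noise or nuisance sources, so
# closed-form recovery statements hold exactly.
noisefree_spec <- function(seed = 1, ...) {
  tiny_spec(
    seed = seed,
    noise_sd = 0, region_signal_sd = 0, map_topography_sd = 0,
    global_signal_sd = 0, motion_loading = 0, tissue_loading = 0,
    cohort_scale = c(A = 1, B = 1), cohort_offset = c(A = 0, B = 0),
    ...
  )
}

# Build a conn_map_set directly from a subjects x voxels matrix.
toy_map_set <- function(values, group, cohort = NULL) {
  n <- nrow(values)
  v <- ncol(values)
  if (is.null(cohort)) cohort <- rep("A", n)
  mask <- array(TRUE, dim = c(v, 1, 1))
  structure(
    list(
      t = values, beta = values, stat = "t", mask = mask,
      grid_shape = dim(mask), voxel_size_mm = 3,
      participants = data.frame(
        subject_id = sprintf("s%02d", seq_len(n)),
        group = group, cohort = cohort, age = 30, education_years = 12,
        stringsAsFactors = FALSE
      ),
      seed_label = "seed", fwhm_mm = 0,
      standardized = FALSE, standardize_mode = "none", demeaned = FALSE
    ),
    class = "conn_map_set"
  )
}
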