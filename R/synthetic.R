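#' Specification of a synthetic two-cohort RSFC study
#'
#' Collects every parameter of the synthetic-study generator: grid geometry,
#' subject counts per group (blind, sighted) and cohort (A, B), acquisition
#' parameters per cohort, the planted per-region connectivity effects, noise
#' and nuisance scales, cohort (site) effects, an education covariate
#' coupling, and optional subject subgroups (clades).
#'
#' The defaults emulate the study design the package targets: cohort A with
#' 13 blind and 18 sighted subjects scanned at TR 3 s for 180 volumes,
#' cohort B with 12 blind and 13 sighted at TR 2 s for 240 volumes (25
#' blind and 31 sighted in total), spatially smooth noise of 6 mm FWHM, an
#' affine site effect on cohort B, and planted regions in which the blind
#' group has both a higher mean connectivity weight and a 2.2-fold higher
#' weight standard deviation.
#'
#' @param grid_shape 3 positive integers, image grid in voxels.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_blind_A,n_sighted_A,n_blind_B,n_sighted_B subject counts (>= 2).
#' @param tr_by_cohort named numeric, repetition time in seconds per cohort.
#' @param n_vols_by_cohort named integer, timepoints per cohort.  The
#'   acquisition length is deliberately a parameter rather than a constant.
#' @param n_parcels number of gray-matter parcels in the generated atlas.
#' @param region_effects data frame with columns `region`, `mean_blind`,
#'   `mean_sighted`, `sd_blind`, `sd_sighted`, `edu` (logical: does the
#'   education covariate load on this region).  Regions absent from the
#'   table get zero-mean, zero-sd weights.
#' @param noise_fwhm_mm spatial smoothness (FWHM, mm) of the voxel noise.
#' @param noise_sd temporal noise scale before spatial smoothing.
#' @param region_signal_sd scale of the per-region fluctuation shared by
#'   voxels of one parcel (gives distinct seeds distinct time courses).
#' @param global_signal_sd loading of a brain-wide physiological signal
#'   present in every voxel (gray and tissue compartments alike); the
#'   component global-signal regression is designed to remove.
#' @param map_topography_sd SD of a smooth, study-level voxelwise
#'   connectivity topography added to every subject's seed coupling: the
#'   stable spatial structure real connectivity maps carry.  It leaves
#'   between-subject variances untouched but stabilizes each subject's
#'   map SD, as rich within-map structure does in real data.
#' @param motion_loading,tissue_loading couplings of the motion trace and
#'   the white-matter/ventricle signals into gray-matter voxels.
#' @param cohort_scale,cohort_offset named numerics: affine site effect
#'   applied to every voxel time series of a cohort.
#' @param education_slope named numeric (`blind`, `sighted`): increment of
#'   the connectivity weight per year of education (centred at 14 years)
#'   in regions flagged `edu`.
#' @param clades `NULL`, or `list(group =, effects =)` where `effects` is a
#'   data frame with columns `clade`, `region`, `offset`: subjects of
#'   `group` are split evenly at random across clades and receive the
#'   clade's weight offsets (planted fingerprint subgroups).
#' @param rng_seed integer; the whole study is reproducible from it.
#' @return an object of class `synthetic_spec` (a validated list).
#' @seealso [simulate_study()], [make_atlas()]
#' @export
synthetic_spec <- function(grid_shape = c(10, 10, 8),
                           voxel_size_mm = 3,
                           n_blind_A = 13, n_sighted_A = 18,
                           n_blind_B = 12, n_sighted_B = 13,
                           tr_by_cohort = c(A = 3, B = 2),
                           n_vols_by_cohort = c(A = 180, B = 240),
                           n_parcels = 17,
                           region_effects = default_region_effects(n_parcels),
                           noise_fwhm_mm = 2,
                           noise_sd = 1.4,
                           region_signal_sd = 0.35,
                           map_topography_sd = 0.8,
                           global_signal_sd = 0.5,
                           motion_loading = 0.1,
                           tissue_loading = 0.1,
                           cohort_scale = c(A = 1, B = 1.3),
                           cohort_offset = c(A = 0, B = 10),
                           education_slope = c(blind = 0.05, sighted = 0),
                           clades = NULL,
                           rng_seed = 1L) {
  counts <- c(n_blind_A, n_sighted_A, n_blind_B, n_sighted_B)
  if (any(counts < 2)) {
    stop("all four group-by-cohort subject counts must be >= 2", call. = FALSE)
  }
  stopifnot(
    length(grid_shape) == 3, all(grid_shape > 0), voxel_size_mm > 0,
    all(c("A", "B") %in% names(tr_by_cohort)),
    all(c("A", "B") %in% names(n_vols_by_cohort)),
    noise_fwhm_mm >= 0, noise_sd >= 0, region_signal_sd >= 0
  )
  re <- as.data.frame(region_effects)
  needed <- c("region", "mean_blind", "mean_sighted", "sd_blind", "sd_sighted")
  if (!all(needed %in% names(re))) {
    stop(
      "region_effects needs columns ",
      paste(needed, collapse = ", "), call. = FALSE
    )
  }
  if (is.null(re$edu)) re$edu <- FALSE
  if (any(re$sd_blind < 0) || any(re$sd_sighted < 0)) {
    stop("planted weight standard deviations must be >= 0", call. = FALSE)
  }
  if (any(re$region > n_parcels)) {
    stop("region_effects refers to regions beyond n_parcels", call. = FALSE)
  }
  if (length(education_slope) == 1L) {
    education_slope <- c(blind = unname(education_slope), sighted = 0)
  }
  if (!is.null(clades)) {
    stopifnot(
      is.list(clades), clades$group %in% c("blind", "sighted"),
      all(c("clade", "region", "offset") %in% names(clades$effects))
    )
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
      n_blind_A = n_blind_A, n_sighted_A = n_sighted_A,
      n_blind_B = n_blind_B, n_sighted_B = n_sighted_B,
      tr_by_cohort = tr_by_cohort, n_vols_by_cohort = n_vols_by_cohort,
      n_parcels = as.integer(n_parcels), region_effects = re,
      noise_fwhm_mm = noise_fwhm_mm, noise_sd = noise_sd,
      region_signal_sd = region_signal_sd,
      map_topography_sd = map_topography_sd,
      global_signal_sd = global_signal_sd,
      motion_loading = motion_loading, tissue_loading = tissue_loading,
      cohort_scale = cohort_scale, cohort_offset = cohort_offset,
      education_slope = education_slope, clades = clades,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synthetic_spec"
  )
}

#' Default planted region effects
#'
#' The default effect table used by [synthetic_spec()]: parcel 1 is the
#' seed (weight fixed at 1 for every subject), parcels 3 and 4 carry a
#' coupled effect (higher blind mean and a 2.2-fold higher blind weight SD,
#' i.e. a planted variance ratio of 4.84), parcel 6 is the
#' education-coupled region (low intrinsic weight SD, so the covariate
#' dominates there), and all remaining parcels are null: their baseline
#' means differ from parcel to parcel (the shared connectivity profile)
#' but are identical across groups, as are their SDs.  Effect magnitudes are kept small relative to the overall map
#' scale so the per-subject map standardization does not feed planted
#' weight variability back into null regions.
#'
#' @param n_parcels number of parcels the table should cover.
#' @return data frame understood by [synthetic_spec()].
#' @export
default_region_effects <- function(n_parcels = 17) {
  # heterogeneous baseline means, identical across groups: the shared
  # mean connectivity profile all subjects carry (null regions differ in
  # mean level but not between groups)
  base_mean <- 0.05 + 0.45 * ((seq_len(n_parcels) * 7) %% n_parcels) /
    max(1, n_parcels - 1)
  re <- data.frame(
    region = seq_len(n_parcels),
    mean_blind = base_mean, mean_sighted = base_mean,
    sd_blind = 0.25, sd_sighted = 0.25,
    edu = FALSE
  )
  re[1, c("mean_blind", "mean_sighted")] <- 1
  re[1, c("sd_blind", "sd_sighted")] <- 0
  planted <- intersect(c(3, 4, 12), re$region)
  re[planted, "mean_blind"] <- 0.70
  re[planted, "mean_sighted"] <- 0.05
  re[planted, "sd_blind"] <- 0.66
  re[planted, "sd_sighted"] <- 0.30
  if (n_parcels >= 6) {
    re[6, "edu"] <- TRUE
    re[6, c("sd_blind", "sd_sighted")] <- 0.15
    re[6, c("mean_blind", "mean_sighted")] <- 0.1
  }
  # control-seed parcels: no coupling to the seed network at all, so
  # RSFC analyses seeded there are independent of the designated seed's
  # effects (the role nonvisual control areas play in a cross-seed
  # specificity analysis)
  ctrl <- intersect(c(5, 10, 15), seq_len(n_parcels))
  re[ctrl, c("mean_blind", "mean_sighted", "sd_blind", "sd_sighted")] <- 0
  re
}

#' Default planted clade structure
#'
#' Three fingerprint subgroups for the blind group, each marked by an
#' antisymmetric two-region offset pattern (one region up, another down),
#' so the subgroups differ in profile shape, not just level.
#'
#' @param offset weight offset magnitude.
#' @param regions three region labels carrying the patterns.
#' @return a `clades` list understood by [synthetic_spec()].
#' @export
default_clades <- function(offset = 1.5, regions = c(8, 9, 10)) {
  list(
    group = "blind",
    effects = data.frame(
      clade = rep(1:3, each = 2),
      region = c(
        regions[1], regions[2], regions[2], regions[3],
        regions[3], regions[1]
      ),
      offset = rep(c(offset, -offset), 3)
    )
  )
}

# Unit-variance Gaussian signal band-limited to [low, high] Hz: white
# complex spectrum inside the band, zero outside, inverse FFT, z-scored.
band_limited_signal <- function(n, tr, low = 0.01, high = 0.1) {
  freq <- (seq_len(n) - 1) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq) # fold to [0, Nyquist]
  keep <- freq >= low & freq <= high
  spec <- complex(
    real = stats::rnorm(n),
    imaginary = stats::rnorm(n)
  )
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE))
  zscore(x)
}

# Draw one subject's true connectivity weight per parcel.
draw_weights <- function(spec, group, education, clade = NA_integer_) {
  w <- numeric(spec$n_parcels)
  re <- spec$region_effects
  mu <- if (group == "blind") re$mean_blind else re$mean_sighted
  sd <- if (group == "blind") re$sd_blind else re$sd_sighted
  w[re$region] <- stats::rnorm(nrow(re), mu, sd)
  slope <- spec$education_slope[[group]]
  if (slope != 0 && any(re$edu)) {
    w[re$region[re$edu]] <- w[re$region[re$edu]] + slope * (education - 14)
  }
  if (!is.null(spec$clades) && !is.na(clade) && group == spec$clades$group) {
    eff <- spec$clades$effects
    eff <- eff[eff$clade == clade, , drop = FALSE]
    w[eff$region] <- w[eff$region] + eff$offset
  }
  w
}

#' Simulate one subject's resting-state scan session
#'
#' Generates a 4D BOLD array on the atlas grid.  Each gray-matter voxel is
#' `w(region) * s(t) + r_region(t) + nuisance couplings + noise`, where
#' `s(t)` is the subject's seed time course (a unit-variance Gaussian
#' process band-limited to 0.01-0.1 Hz, so the analysis bandpass preserves
#' it), `r_region(t)` is a shared per-parcel fluctuation, nuisance
#' couplings tie the voxel to the motion trace and to white-matter and
#' ventricle signals, and the noise is temporally white and spatially
#' smoothed to the requested FWHM.  White-matter and ventricle voxels carry
#' their compartment signals plus noise.  The cohort's affine site effect
#' (scale, then offset) is applied last.  Motion parameters are smooth
#' random walks, six columns, one row per timepoint.
#'
#' @param spec a [synthetic_spec()].
#' @param subject_row one row of a participants table (`subject_id`,
#'   `group`, `cohort`, `age`, `education_years`, optionally `clade`).
#' @param atlas a [make_atlas()] result on `spec$grid_shape`.
#' @param weights optional precomputed per-parcel weight vector; drawn via
#'   the spec's planted effects when omitted.
#' @param topography optional 3D array: voxelwise increment to the seed
#'   coupling (the study-level connectivity topography generated by
#'   [simulate_study()]); zero when omitted.
#' @return an object of class `scan_session`: list with `bold` (4D array),
#'   `tr`, `motion` (T x 6), the subject metadata, and the true `weights`
#'   and `seed_signal` used (ground truth for tests).
#' @export
simulate_session <- function(spec, subject_row, atlas, weights = NULL,
                             topography = NULL) {
  for (f in c("subject_id", "group", "cohort", "education_years")) {
    if (is.null(subject_row[[f]]) || is.na(subject_row[[f]])) {
      stop("subject_row is missing required field '", f, "'", call. = FALSE)
    }
  }
  cohort <- as.character(subject_row$cohort)
  group <- as.character(subject_row$group)
  tr <- spec$tr_by_cohort[[cohort]]
  nt <- spec$n_vols_by_cohort[[cohort]]
  d <- spec$grid_shape
  nvox <- prod(d)
  if (is.null(weights)) {
    weights <- draw_weights(
      spec, group, subject_row$education_years,
      if (is.null(subject_row$clade)) NA_integer_ else subject_row$clade
    )
  }

  s <- band_limited_signal(nt, tr)
  parc <- as.integer(atlas$parcellation)
  # per-parcel fluctuations; the seed parcel has none, so its BOLD is
  # exactly w * s(t) (+ noise), as the extraction contract requires
  rg <- matrix(0, nt, spec$n_parcels)
  if (spec$region_signal_sd > 0) {
    for (g in seq_len(spec$n_parcels)) {
      if (g != atlas$seed_parcel) {
        rg[, g] <- spec$region_signal_sd * band_limited_signal(nt, tr)
      }
    }
  }
  wm_sig <- band_limited_signal(nt, tr)
  vent_sig <- band_limited_signal(nt, tr)
  glob_sig <- band_limited_signal(nt, tr)

  motion <- vapply(
    1:6,
    function(i) cumsum(stats::rnorm(nt, sd = 0.05)),
    numeric(nt)
  )

  # voxels x time; every voxel of a parcel shares w * s(t) + r_region(t)
  bold <- matrix(0, nvox, nt)
  gray_idx <- which(parc > 0L)
  region_ts <- t(rg + outer(s, weights)) # parcels x time
  bold[gray_idx, ] <- region_ts[parc[gray_idx], , drop = FALSE]
  if (!is.null(topography)) {
    bold[gray_idx, ] <- bold[gray_idx, ] + outer(topography[gray_idx], s)
  }
  if (spec$tissue_loading > 0) {
    lw <- stats::rnorm(length(gray_idx), 0, spec$tissue_loading)
    lv <- stats::rnorm(length(gray_idx), 0, spec$tissue_loading)
    bold[gray_idx, ] <- bold[gray_idx, ] + outer(lw, wm_sig) + outer(lv, vent_sig)
  }
  if (spec$motion_loading > 0) {
    m1 <- zscore(rowMeans(scale(motion)))
    lm_ <- stats::rnorm(length(gray_idx), 0, spec$motion_loading)
    bold[gray_idx, ] <- bold[gray_idx, ] + outer(lm_, m1)
  }
  bold[which(atlas$wm_mask), ] <-
    rep(wm_sig, each = sum(atlas$wm_mask))
  bold[which(atlas$ventricle_mask), ] <-
    rep(vent_sig, each = sum(atlas$ventricle_mask))
  if (spec$global_signal_sd > 0) {
    bold <- bold + spec$global_signal_sd *
      matrix(glob_sig, nvox, nt, byrow = TRUE)
  }

  if (spec$noise_sd > 0) {
    eps <- array(stats::rnorm(nvox * nt), dim = c(d, nt))
    if (spec$noise_fwhm_mm > 0) {
      # smooth, then restore unit variance so noise_sd is the per-voxel
      # scale regardless of the smoothness setting
      eps <- smooth_volume(eps, spec$noise_fwhm_mm, spec$voxel_size_mm)
      sigma <- fwhm_to_sigma(spec$noise_fwhm_mm) / spec$voxel_size_mm
      eps <- eps / sqrt(sum(gaussian_kernel_1d(sigma)^2)^3)
    }
    bold <- bold + spec$noise_sd * matrix(eps, nvox, nt)
  }

  bold <- spec$cohort_scale[[cohort]] * bold + spec$cohort_offset[[cohort]]
  dim(bold) <- c(d, nt)

  structure(
    list(
      bold = bold, tr = tr, motion = motion,
      subject_id = as.character(subject_row$subject_id),
      group = group, cohort = cohort,
      age = subject_row$age,
      education_years = subject_row$education_years,
      weights = weights, seed_signal = s
    ),
    class = "scan_session"
  )
}

#' Simulate a full two-cohort, two-group synthetic study
#'
#' Builds the atlas, draws the participants table (group, cohort, age,
#' education years, optional planted clade), simulates every subject's
#' session via [simulate_session()], and records the ground truth needed by
#' recovery tests: the true weight matrix, the planted per-region variance
#' ratio (including the education contribution, education years being
#' uniform on 8-20), and the planted clade labels.
#'
#' @param spec a [synthetic_spec()]; `spec$rng_seed` makes the study fully
#'   reproducible.
#' @return an object of class `varconn_study`: list with `sessions`,
#'   `participants` (data frame), `atlas`, `ground_truth` (list
#'   `weight_by_subject_region`, `true_variance_ratio_by_region`,
#'   `true_clade_by_subject`) and the `spec`.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    atlas <- make_atlas(spec$grid_shape, spec$n_parcels,
      voxel_size_mm = spec$voxel_size_mm
    )
    n <- c(
      blind_A = spec$n_blind_A, sighted_A = spec$n_sighted_A,
      blind_B = spec$n_blind_B, sighted_B = spec$n_sighted_B
    )
    total <- sum(n)
    participants <- data.frame(
      subject_id = sprintf("sub-%03d", seq_len(total)),
      group = rep(
        c("blind", "sighted", "blind", "sighted"), n
      ),
      cohort = rep(c("A", "A", "B", "B"), n),
      age = sample(22:63, total, replace = TRUE),
      education_years = sample(8:20, total, replace = TRUE),
      stringsAsFactors = FALSE
    )
    participants$clade <- NA_integer_
    if (!is.null(spec$clades)) {
      in_grp <- participants$group == spec$clades$group
      k <- max(spec$clades$effects$clade)
      participants$clade[in_grp] <-
        sample(rep(seq_len(k), length.out = sum(in_grp)))
    }
    topography <- NULL
    if (spec$map_topography_sd > 0) {
      topo <- array(stats::rnorm(prod(spec$grid_shape)), dim = spec$grid_shape)
      if (spec$noise_fwhm_mm > 0) {
        topo <- smooth_volume(topo, spec$noise_fwhm_mm, spec$voxel_size_mm)
      }
      gv <- topo[atlas$gray_mask]
      # remove per-parcel means: between-parcel profile structure is owned
      # by region_effects; the topography is within-parcel texture only,
      # so parcel-mean time courses stay decoupled from the seed signal
      gv <- gv - stats::ave(gv, atlas$parcellation[atlas$gray_mask])
      topo[atlas$gray_mask] <- gv / stats::sd(gv) * spec$map_topography_sd
      topo[!atlas$gray_mask] <- 0
      topography <- topo
    }
    weights <- matrix(0, total, spec$n_parcels,
      dimnames = list(participants$subject_id, NULL)
    )
    sessions <- vector("list", total)
    for (i in seq_len(total)) {
      row <- participants[i, ]
      w <- draw_weights(
        spec, row$group, row$education_years, row$clade
      )
      weights[i, ] <- w
      sessions[[i]] <- simulate_session(spec, row, atlas,
        weights = w, topography = topography
      )
    }
    names(sessions) <- participants$subject_id

    re <- spec$region_effects
    var_edu <- (13^2 - 1) / 12 # variance of a uniform integer on 8..20
    sl <- spec$education_slope
    vb <- re$sd_blind^2 + ifelse(re$edu, sl[["blind"]]^2 * var_edu, 0)
    vs <- re$sd_sighted^2 + ifelse(re$edu, sl[["sighted"]]^2 * var_edu, 0)
    ratio <- rep(NA_real_, spec$n_parcels)
    ratio[re$region] <- ifelse(vs > 0, vb / vs, NA_real_)

    structure(
      list(
        sessions = sessions,
        participants = participants,
        atlas = atlas,
        ground_truth = list(
          weight_by_subject_region = weights,
          topography = topography,
          true_variance_ratio_by_region = ratio,
          true_clade_by_subject = stats::setNames(
            participants$clade, participants$subject_id
          )
        ),
        spec = spec
      ),
      class = "varconn_study"
    )
  })
}

#' @export
print.varconn_study <- function(x, ...) {
  p <- x$participants
  cat(sprintf(
    "varconn synthetic study: %d subjects (%d blind, %d sighted; cohorts %s)\n",
    nrow(p), sum(p$group == "blind"), sum(p$group == "sighted"),
    paste(names(table(p$cohort)), table(p$cohort), sep = ":", collapse = ", ")
  ))
  print(x$atlas)
  invisible(x)
}
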