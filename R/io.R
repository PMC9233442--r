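#' Pipeline configuration
#'
#' Validated container for the tunable analysis parameters.  Defaults are
#' the package's standard analysis settings: a 0.01-0.1 Hz bandpass, 6 mm
#' FWHM map smoothing, no global-signal regression, 10,000 permutation /
#' Monte Carlo iterations (raise to 100,000 for production permutation
#' tests), cluster-forming voxel p of 0.005 and cluster alpha of 0.05.
#'
#' @param bandpass_low_hz,bandpass_high_hz bandpass edges in Hz.
#' @param smoothing_fwhm_mm spatial smoothing of subject maps, mm FWHM.
#' @param use_global_signal add the global mean as a nuisance regressor.
#' @param n_permutations iterations for permutation/Monte Carlo nulls.
#' @param cluster_alpha family-wise alpha for cluster-extent correction.
#' @param voxel_p cluster-forming voxel-level p threshold.
#' @param rng_seed integer seed for stochastic stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(bandpass_low_hz = 0.01, bandpass_high_hz = 0.1,
                            smoothing_fwhm_mm = 6, use_global_signal = FALSE,
                            n_permutations = 10000, cluster_alpha = 0.05,
                            voxel_p = 0.005, rng_seed = 1L) {
  if (!(bandpass_low_hz > 0 && bandpass_low_hz < bandpass_high_hz)) {
    stop("need 0 < bandpass_low_hz < bandpass_high_hz", call. = FALSE)
  }
  if (n_permutations < 100) {
    stop("n_permutations must be >= 100", call. = FALSE)
  }
  if (!(cluster_alpha > 0 && cluster_alpha < 1 && voxel_p > 0 && voxel_p < 1)) {
    stop("cluster_alpha and voxel_p must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      bandpass_low_hz = bandpass_low_hz,
      bandpass_high_hz = bandpass_high_hz,
      smoothing_fwhm_mm = smoothing_fwhm_mm,
      use_global_signal = isTRUE(use_global_signal),
      n_permutations = as.integer(n_permutations),
      cluster_alpha = cluster_alpha, voxel_p = voxel_p,
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file with a flat parameter namespace.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) {
    stop(
      "unknown configuration keys: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(pipeline_config, vals)
}

nifti_with_voxels <- function(arr, voxel_size_mm, tr = NULL) {
  im <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4L) {
    c(rep(voxel_size_mm, 3), if (is.null(tr)) 1 else tr)
  } else {
    rep(voxel_size_mm, 3)
  }
  RNifti::pixdim(im) <- pd
  im
}

#' Write a statistic map to NIfTI
#'
#' Values are stored as 64-bit floats so the in-mask values round-trip
#' losslessly; voxels outside the mask are written as NaN.
#'
#' @param map 3D array (NA/NaN outside the analysis mask).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size_mm isotropic voxel size recorded in the header.
#' @return `path`, invisibly.
#' @export
save_stat_map <- function(map, path, voxel_size_mm = 3) {
  stopifnot(length(dim(map)) == 3L)
  im <- nifti_with_voxels(map * 1.0, voxel_size_mm)
  RNifti::writeNifti(im, path, datatype = "double")
  invisible(path)
}

#' Read a statistic map from NIfTI
#'
#' @param path NIfTI file written by [save_stat_map()] (or compatible).
#' @param reference optional 3D array or atlas whose grid the map must
#'   match; a mismatch is an error.
#' @return a plain 3D array with the header voxel size attached as
#'   attribute `voxel_size_mm`.
#' @export
load_stat_map <- function(path, reference = NULL) {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim = dim(im))
  if (!is.null(reference)) {
    ref_dim <- if (inherits(reference, "varconn_atlas")) {
      reference$grid_shape
    } else {
      dim(reference)
    }
    if (!identical(as.integer(dim(arr)), as.integer(ref_dim))) {
      stop(sprintf(
        "grid mismatch: map %s is %s, reference is %s",
        path, paste(dim(arr), collapse = "x"),
        paste(ref_dim, collapse = "x")
      ), call. = FALSE)
    }
  }
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(im)[1]
  arr
}

#' Write a simulated study to disk
#'
#' Emits the on-disk layout the readers expect: one 4D BOLD NIfTI and one
#' 6-column whitespace-delimited motion file per subject, a
#' `participants.tsv`, the atlas images (integer parcellation, 0/1 masks),
#' and a `ground_truth.tsv` with the true subject-by-region weights and
#' planted clades.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "varconn_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- study$atlas$voxel_size_mm
  utils::write.table(
    study$participants[
      , c("subject_id", "group", "cohort", "age", "education_years")
    ],
    file.path(dir, "participants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (s in study$sessions) {
    im <- nifti_with_voxels(s$bold, vx, tr = s$tr)
    RNifti::writeNifti(
      im, file.path(dir, paste0(s$subject_id, "_bold.nii.gz"))
    )
    utils::write.table(
      s$motion, file.path(dir, paste0(s$subject_id, "_motion.txt")),
      sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  a <- study$atlas
  RNifti::writeNifti(
    nifti_with_voxels(a$parcellation + 0L, vx),
    file.path(dir, "atlas_parcellation.nii.gz")
  )
  for (m in c("seed_mask", "gray_mask", "wm_mask", "ventricle_mask")) {
    RNifti::writeNifti(
      nifti_with_voxels(a[[m]] + 0L, vx), file.path(dir, paste0(m, ".nii.gz"))
    )
  }
  gt <- as.data.frame(study$ground_truth$weight_by_subject_region)
  names(gt) <- paste0("region_", seq_len(ncol(gt)))
  gt <- cbind(
    subject_id = study$participants$subject_id,
    clade = study$ground_truth$true_clade_by_subject, gt
  )
  utils::write.table(
    gt, file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Load and validate a study directory
#'
#' Reads `participants.tsv` and the atlas images, checks the controlled
#' group/cohort vocabularies, verifies that every subject's BOLD and
#' motion files exist, share the atlas grid, and agree on timepoint
#' counts.  Validation failures are descriptive errors naming the subject.
#'
#' @param root directory produced by [write_study()] (or laid out the
#'   same way).
#' @return an object of class `study_layout`: participants, atlas, and
#'   per-subject file paths; load sessions with [load_session()].
#' @export
load_study <- function(root) {
  pfile <- file.path(root, "participants.tsv")
  if (!file.exists(pfile)) {
    stop("participants.tsv not found in ", root, call. = FALSE)
  }
  participants <- utils::read.delim(pfile, stringsAsFactors = FALSE)
  bad_group <- setdiff(unique(participants$group), c("blind", "sighted"))
  if (length(bad_group)) {
    stop(
      "unknown group label(s) ", paste(bad_group, collapse = ", "),
      "; allowed: blind, sighted", call. = FALSE
    )
  }
  bad_cohort <- setdiff(unique(participants$cohort), c("A", "B"))
  if (length(bad_cohort)) {
    stop(
      "unknown cohort label(s) ", paste(bad_cohort, collapse = ", "),
      "; allowed: A, B", call. = FALSE
    )
  }
  parc_path <- file.path(root, "atlas_parcellation.nii.gz")
  if (!file.exists(parc_path)) {
    stop("atlas_parcellation.nii.gz not found in ", root, call. = FALSE)
  }
  parc_img <- RNifti::readNifti(parc_path)
  grid <- dim(parc_img)
  voxel <- RNifti::pixdim(parc_img)[1]
  masks <- lapply(
    c(
      seed_mask = "seed_mask", gray_mask = "gray_mask",
      wm_mask = "wm_mask", ventricle_mask = "ventricle_mask"
    ),
    function(m) {
      p <- file.path(root, paste0(m, ".nii.gz"))
      if (!file.exists(p)) stop(m, ".nii.gz not found in ", root, call. = FALSE)
      im <- RNifti::readNifti(p)
      if (!identical(dim(im), grid)) {
        stop(m, " grid does not match the parcellation grid", call. = FALSE)
      }
      array(as.numeric(im) > 0, dim = grid)
    }
  )
  parc <- array(as.integer(parc_img), dim = grid)
  atlas <- structure(
    list(
      parcellation = parc, seed_mask = masks$seed_mask,
      gray_mask = masks$gray_mask, wm_mask = masks$wm_mask,
      ventricle_mask = masks$ventricle_mask,
      grid_shape = as.integer(grid), voxel_size_mm = voxel,
      n_parcels = max(parc), seed_parcel = {
        sp <- unique(parc[masks$seed_mask])
        if (length(sp) == 1L) sp else 1L
      }
    ),
    class = "varconn_atlas"
  )
  bold_paths <- file.path(root, paste0(participants$subject_id, "_bold.nii.gz"))
  motion_paths <- file.path(root, paste0(participants$subject_id, "_motion.txt"))
  for (i in seq_len(nrow(participants))) {
    sid <- participants$subject_id[i]
    if (!file.exists(bold_paths[i])) {
      stop("missing BOLD file for subject ", sid, call. = FALSE)
    }
    if (!file.exists(motion_paths[i])) {
      stop("missing motion file for subject ", sid, call. = FALSE)
    }
    hdr <- RNifti::niftiHeader(bold_paths[i])
    bdim <- hdr$dim[2:(hdr$dim[1] + 1)]
    if (!identical(as.integer(bdim[1:3]), as.integer(grid))) {
      stop(
        "BOLD grid mismatch for subject ", sid, ": ",
        paste(bdim[1:3], collapse = "x"), " vs atlas ",
        paste(grid, collapse = "x"),
        call. = FALSE
      )
    }
    n_mot <- length(readLines(motion_paths[i]))
    if (n_mot != bdim[4]) {
      stop(sprintf(
        "motion/BOLD length mismatch for subject %s: %d motion rows, %d volumes",
        sid, n_mot, bdim[4]
      ), call. = FALSE)
    }
  }
  structure(
    list(
      root = root, participants = participants, atlas = atlas,
      bold_paths = stats::setNames(bold_paths, participants$subject_id),
      motion_paths = stats::setNames(motion_paths, participants$subject_id)
    ),
    class = "study_layout"
  )
}

#' Load one subject's session from a study layout
#'
#' @param layout a [load_study()] result.
#' @param subject_id subject to load.
#' @return a `scan_session` (without simulation ground truth).
#' @export
load_session <- function(layout, subject_id) {
  if (!subject_id %in% layout$participants$subject_id) {
    stop("unknown subject ", subject_id, call. = FALSE)
  }
  row <- layout$participants[layout$participants$subject_id == subject_id, ]
  im <- RNifti::readNifti(layout$bold_paths[[subject_id]])
  motion <- as.matrix(utils::read.table(layout$motion_paths[[subject_id]]))
  dimnames(motion) <- NULL
  structure(
    list(
      bold = array(as.numeric(im), dim = dim(im)),
      tr = RNifti::pixdim(im)[4],
      motion = motion,
      subject_id = subject_id, group = row$group, cohort = row$cohort,
      age = row$age, education_years = row$education_years
    ),
    class = "scan_session"
  )
}

# Machine-readable stage log: parameters + seed + version, enough to
# re-run a deterministic stage identically.
write_stage_log <- function(dir, stage, params) {
  log <- list(
    stage = stage,
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    varconn_version = as.character(utils::packageVersion("varconn")),
    r_version = R.version.string,
    params = params
  )
  yaml::write_yaml(log, file.path(dir, paste0(stage, "_log.yaml")))
  invisible(log)
}
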