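#' Bandpass filter a time series (zero phase, frequency domain)
#'
#' Retains fluctuations between `low_hz` and `high_hz` using a zero-phase
#' frequency-domain filter with a raised-cosine transition band of width
#' `transition_hz` on either side.  The DC component is always removed.
#'
#' @param x numeric vector, or matrix with time down the rows (each column
#'   filtered independently).
#' @param tr sampling interval in seconds.
#' @param low_hz,high_hz passband edges in Hz; `high_hz` must lie below
#'   the Nyquist frequency `1/(2 tr)`.
#' @param transition_hz width of the raised-cosine roll-off.
#' @return filtered series, same shape as `x`.
#' @export
bandpass <- function(x, tr, low_hz = 0.01, high_hz = 0.1,
                     transition_hz = 0.005) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= 1 / (2 * tr)) {
    stop(sprintf(
      "high_hz = %.3f Hz is not below the Nyquist frequency %.3f Hz for TR %.3g s",
      high_hz, 1 / (2 * tr), tr
    ), call. = FALSE)
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f) # fold to [0, Nyquist]
  H <- numeric(n)
  H[f >= low_hz & f <= high_hz] <- 1
  up <- f > low_hz - transition_hz & f < low_hz
  H[up] <- 0.5 * (1 - cos(pi * (f[up] - (low_hz - transition_hz)) / transition_hz))
  down <- f > high_hz & f < high_hz + transition_hz
  H[down] <- 0.5 * (1 + cos(pi * (f[down] - high_hz) / transition_hz))
  H[f == 0] <- 0
  if (ncol(xm) > 2L * n) {
    # many series: apply the (cached) real filter matrix with one
    # matrix product instead of per-column FFTs
    out <- filter_matrix(n, H) %*% xm
  } else {
    out <- Re(stats::mvfft(stats::mvfft(xm) * H, inverse = TRUE)) / n
  }
  if (vec) out[, 1] else out
}

filter_matrix_cache <- new.env(parent = emptyenv())

# Real time-domain operator of the zero-phase frequency response H.
filter_matrix <- function(n, H) {
  key <- paste0(n, ":", digest_vec(H))
  hit <- filter_matrix_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  Fm <- Re(stats::mvfft(H * stats::mvfft(diag(n)), inverse = TRUE)) / n
  filter_matrix_cache[[key]] <- Fm
  Fm
}

digest_vec <- function(x) {
  paste0(length(x), "-", format(sum(x * seq_along(x)), digits = 15), "-",
    format(sum(x), digits = 15))
}

#' Preprocess a scan session
#'
#' Drops the first `drop_vols` volumes (non-steady-state magnetization)
#' from the BOLD data and the motion table, then bandpass filters every
#' voxel time series.
#'
#' @param session a `scan_session`.
#' @param low_hz,high_hz bandpass edges (see [bandpass()]).
#' @param drop_vols initial volumes to discard.
#' @return the session with filtered `bold`, trimmed `motion`, and
#'   `preprocessed = TRUE`.
#' @export
preprocess_session <- function(session, low_hz = 0.01, high_hz = 0.1,
                               drop_vols = 2L) {
  if (isTRUE(session$preprocessed)) {
    return(session)
  }
  d <- dim(session$bold)
  keep <- (drop_vols + 1L):d[4]
  bold <- session$bold[, , , keep, drop = FALSE]
  nt <- length(keep)
  y <- t(matrix(bold, prod(d[1:3]), nt))
  y <- bandpass(y, session$tr, low_hz, high_hz)
  session$bold <- array(t(y), dim = c(d[1:3], nt))
  session$motion <- session$motion[keep, , drop = FALSE]
  if (!is.null(session$seed_signal)) {
    session$seed_signal <- session$seed_signal[keep]
  }
  session$preprocessed <- TRUE
  session
}

#' Preprocess every session of an in-memory study
#'
#' @inheritParams preprocess_session
#' @param study a `varconn_study`.
#' @return the study with all sessions preprocessed.
#' @export
preprocess_study <- function(study, low_hz = 0.01, high_hz = 0.1,
                             drop_vols = 2L) {
  study$sessions <- lapply(
    study$sessions, preprocess_session,
    low_hz = low_hz, high_hz = high_hz, drop_vols = drop_vols
  )
  study
}

#' Extract the seed predictor time course
#'
#' Spatial mean of the (preprocessed) BOLD signal over the seed mask at
#' each timepoint, z-transformed to mean 0 and SD 1 for use as the GLM
#' predictor.
#'
#' @param session a `scan_session` (or a 4D BOLD array).
#' @param seed_mask logical 3D array, nonempty on the session grid.
#' @return numeric vector, one value per timepoint.
#' @export
extract_seed_timecourse <- function(session, seed_mask) {
  bold <- if (inherits(session, "scan_session")) session$bold else session
  d <- dim(bold)
  if (!any(seed_mask)) {
    stop("seed mask is empty", call. = FALSE)
  }
  y <- matrix(bold, prod(d[1:3]), d[4])[which(seed_mask), , drop = FALSE]
  ts <- colMeans(y)
  if (stats::sd(ts) == 0) {
    stop("seed time course has zero variance", call. = FALSE)
  }
  zscore(ts)
}

#' Build the nuisance design matrix
#'
#' Columns: the six motion parameters, their first derivatives (backward
#' difference, first row 0), the mean white-matter and ventricle signals,
#' optionally the global (whole-grid) mean signal, and an intercept.  All
#' non-intercept columns are z-scored; zero-variance columns are left at
#' zero and flagged as degenerate.
#'
#' @param session a (preprocessed) `scan_session`.
#' @param wm_mask,ventricle_mask nonempty logical 3D arrays.
#' @param use_global add the global mean signal as a regressor.
#' @return numeric matrix, timepoints x columns (15, or 16 with the
#'   global signal), with attribute `degenerate_columns`.
#' @export
build_nuisance_design <- function(session, wm_mask, ventricle_mask,
                                  use_global = FALSE) {
  stopifnot(any(wm_mask), any(ventricle_mask))
  bold <- session$bold
  d <- dim(bold)
  nt <- d[4]
  if (nrow(session$motion) != nt) {
    stop(sprintf(
      "motion table has %d rows but the session has %d timepoints",
      nrow(session$motion), nt
    ), call. = FALSE)
  }
  ymat <- matrix(bold, prod(d[1:3]), nt)
  mot <- session$motion
  dmot <- rbind(0, diff(mot))
  X <- cbind(mot, dmot,
    wm = colMeans(ymat[which(wm_mask), , drop = FALSE]),
    ventricle = colMeans(ymat[which(ventricle_mask), , drop = FALSE])
  )
  colnames(X)[1:12] <- c(paste0("mot", 1:6), paste0("dmot", 1:6))
  if (use_global) {
    X <- cbind(X, global = colMeans(ymat))
  }
  sds <- apply(X, 2, stats::sd)
  degenerate <- colnames(X)[sds == 0]
  for (j in seq_len(ncol(X))) {
    X[, j] <- if (sds[j] > 0) (X[, j] - mean(X[, j])) / sds[j] else 0
  }
  X <- cbind(X, intercept = 1)
  if (length(degenerate)) {
    warning(
      "degenerate (zero-variance) nuisance columns: ",
      paste(degenerate, collapse = ", "),
      call. = FALSE
    )
  }
  if (qr(X)$rank < ncol(X)) {
    warning(
      "nuisance design is rank deficient; a pseudoinverse fit will be used",
      call. = FALSE
    )
  }
  attr(X, "degenerate_columns") <- degenerate
  X
}

#' Per-subject seed connectivity map (voxelwise GLM)
#'
#' Ordinary least squares of every z-scored voxel time series on the seed
#' predictor plus the nuisance design.  The map stores the seed
#' predictor's t statistic and its parameter estimate (beta); both are
#' retrievable downstream.  Voxels with a degenerate (zero-variance)
#' series get NaN and are counted.
#'
#' @param session a (preprocessed) `scan_session`.
#' @param seed_series z-scored seed predictor, length = timepoints.
#' @param nuisance_design matrix from [build_nuisance_design()].
#' @return an object of class `conn_map`: 3D arrays `t` and `beta`,
#'   degrees of freedom `df`, `n_degenerate`, and the subject metadata.
#' @export
seed_glm_map <- function(session, seed_series, nuisance_design) {
  bold <- session$bold
  d <- dim(bold)
  nt <- d[4]
  stopifnot(length(seed_series) == nt, nrow(nuisance_design) == nt)
  Y <- t(matrix(bold, prod(d[1:3]), nt))
  mu <- colMeans(Y)
  sds <- sqrt(pmax(colMeans(Y^2) - mu^2, 0) * nt / (nt - 1))
  ok <- sds > 0 & is.finite(sds)
  Yz <- (Y[, ok, drop = FALSE] -
    rep(mu[ok], each = nt)) / rep(sds[ok], each = nt)
  X <- cbind(seed = seed_series, nuisance_design)
  qx <- qr(X)
  coef <- qr.coef(qx, Yz)
  coef[is.na(coef)] <- 0
  resid <- Yz - X %*% coef
  df <- nt - qx$rank
  sigma2 <- colSums(resid^2) / df
  xtx_inv_11 <- chol2inv(qr.R(qx))[1, 1]
  tval <- coef[1, ] / sqrt(sigma2 * xtx_inv_11)
  t_arr <- array(NaN, dim = d[1:3])
  b_arr <- array(NaN, dim = d[1:3])
  t_arr[ok] <- tval
  b_arr[ok] <- coef[1, ]
  structure(
    list(
      t = t_arr, beta = b_arr, df = df,
      n_degenerate = sum(!ok),
      subject_id = session$subject_id, group = session$group,
      cohort = session$cohort
    ),
    class = "conn_map"
  )
}

#' Smooth a statistic map
#'
#' Gaussian smoothing in mm with in-mask renormalization, so voxels near
#' the mask border are unbiased (the kernel mass falling outside the mask
#' is redistributed).  `fwhm_mm = 0` is the identity.
#'
#' @param map 3D array.
#' @param fwhm_mm kernel FWHM in mm.
#' @param voxel_size_mm voxel size in mm.
#' @param mask optional logical 3D array restricting the smoothing.
#' @return smoothed 3D array.
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size_mm = 3, mask = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) {
    return(map)
  }
  smooth_volume(map, fwhm_mm, voxel_size_mm, mask = mask)
}

#' Compute standardized seed-RSFC maps for a whole study
#'
#' The per-subject pipeline: preprocess (drop initial volumes, bandpass),
#' extract the seed time course, build the nuisance design, fit the
#' voxelwise GLM, and smooth the resulting t and beta maps within the
#' gray-matter mask.  Returns the study's maps as a `conn_map_set` whose
#' rows are subjects and whose columns are in-mask voxels.
#'
#' @param study a `varconn_study` (in-memory) or `study_layout` (on disk).
#' @param seed_mask logical 3D array; defaults to the atlas seed parcel.
#' @param seed_label label recorded on the map set.
#' @param fwhm_mm spatial smoothing FWHM in mm (0 to disable).
#' @param use_global add global-signal regression to the nuisance model.
#' @param low_hz,high_hz bandpass edges.
#' @param stat which statistic downstream group analyses should read by
#'   default: `"t"` (default) or `"beta"`; both are stored.
#' @param standardize site-effect normalization applied to the maps
#'   before smoothing.  `"cohort"` (the pipeline default for group
#'   analyses) removes each cohort's mean map level and average map SD,
#'   eliminating site scale/offset effects while leaving within-cohort
#'   subject differences untouched.  `"subject"` z-normalizes every
#'   individual map to mean 0, SD 1 (the stricter per-subject variant;
#'   its scale estimate is noisier and couples a subject's strong
#'   regional effects into the rest of their map).  `"none"` leaves raw
#'   statistic maps.  `TRUE`/`FALSE` are accepted as `"subject"`/`"none"`.
#'   Normalization constants always come from the unsmoothed maps, whose
#'   larger number of independent voxels estimates the scale precisely.
#' @return an object of class `conn_map_set`.
#' @export
rsfc_maps <- function(study, seed_mask = NULL, seed_label = "seed",
                      fwhm_mm = 6, use_global = FALSE,
                      low_hz = 0.01, high_hz = 0.1, stat = c("t", "beta"),
                      standardize = c("none", "cohort", "subject")) {
  stat <- match.arg(stat)
  if (is.logical(standardize)) {
    standardize <- if (standardize) "subject" else "none"
  }
  standardize <- match.arg(standardize)
  atlas <- study$atlas
  if (is.null(seed_mask)) seed_mask <- atlas$seed_mask
  subject_ids <- study$participants$subject_id
  n <- length(subject_ids)
  mask <- atlas$gray_mask
  nmask <- sum(mask)
  t_mat <- matrix(NA_real_, n, nmask)
  b_mat <- matrix(NA_real_, n, nmask)
  for (i in seq_len(n)) {
    sess <- if (inherits(study, "study_layout")) {
      load_session(study, subject_ids[i])
    } else {
      study$sessions[[subject_ids[i]]]
    }
    sess <- preprocess_session(sess, low_hz, high_hz)
    ts <- extract_seed_timecourse(sess, seed_mask)
    X <- build_nuisance_design(
      sess, atlas$wm_mask, atlas$ventricle_mask,
      use_global = use_global
    )
    cm <- seed_glm_map(sess, ts, X)
    t_mat[i, ] <- cm$t[mask]
    b_mat[i, ] <- cm$beta[mask]
  }
  cohorts <- study$participants$cohort
  row_sds <- function(v) {
    mu <- rowMeans(v)
    sqrt(pmax(rowMeans(v^2) - mu^2, 0) * ncol(v) / (ncol(v) - 1))
  }
  normalize <- function(v) {
    if (standardize == "subject") {
      v <- (v - rowMeans(v)) / row_sds(v)
    } else if (standardize == "cohort") {
      for (ch in unique(cohorts)) {
        idx <- cohorts == ch
        mu <- mean(rowMeans(v[idx, , drop = FALSE]))
        sc <- mean(row_sds(v[idx, , drop = FALSE]))
        v[idx, ] <- (v[idx, ] - mu) / sc
      }
    }
    v
  }
  t_mat <- normalize(t_mat)
  b_mat <- normalize(b_mat)
  if (fwhm_mm > 0) {
    for (i in seq_len(n)) {
      tv <- smooth_map(vol_from_masked(t_mat[i, ], mask), fwhm_mm,
        atlas$voxel_size_mm,
        mask = mask
      )
      bv <- smooth_map(vol_from_masked(b_mat[i, ], mask), fwhm_mm,
        atlas$voxel_size_mm,
        mask = mask
      )
      t_mat[i, ] <- tv[mask]
      b_mat[i, ] <- bv[mask]
    }
  }
  structure(
    list(
      t = t_mat, beta = b_mat, stat = stat,
      mask = mask, grid_shape = atlas$grid_shape,
      voxel_size_mm = atlas$voxel_size_mm,
      participants = study$participants,
      seed_label = seed_label, fwhm_mm = fwhm_mm,
      standardized = standardize != "none",
      standardize_mode = standardize, demeaned = FALSE
    ),
    class = "conn_map_set"
  )
}

#' In-mask value matrix of a map set
#'
#' @param maps a `conn_map_set`.
#' @param stat `"t"` or `"beta"`; defaults to the set's recorded choice.
#' @return numeric matrix, subjects x in-mask voxels.
#' @export
map_values <- function(maps, stat = NULL) {
  maps[[if (is.null(stat)) maps$stat else stat]]
}

#' @export
print.conn_map_set <- function(x, ...) {
  cat(sprintf(
    "conn_map_set: %d subjects x %d in-mask voxels (seed '%s', stat %s%s%s)\n",
    nrow(x$t), ncol(x$t), x$seed_label, x$stat,
    if (x$standardized) ", standardized" else "",
    if (x$demeaned) ", cell-demeaned" else ""
  ))
  invisible(x)
}

#' Per-subject map standardization (site-effect removal)
#'
#' z-normalizes each subject's map across in-mask voxels (mean 0, SD 1 per
#' map).  Any affine per-cohort scale/offset acting on a subject's map is
#' removed exactly by construction.
#'
#' @param maps a `conn_map_set` with at least 2 subjects per cohort.
#' @return the standardized `conn_map_set`.
#' @export
site_standardize <- function(maps) {
  if (any(table(maps$participants$cohort) < 2)) {
    stop("need >= 2 subjects per cohort", call. = FALSE)
  }
  for (which in c("t", "beta")) {
    m <- maps[[which]]
    mu <- rowMeans(m)
    sd <- sqrt(rowMeans(m^2) - mu^2) * sqrt(ncol(m) / (ncol(m) - 1))
    if (any(sd == 0)) {
      stop("cannot standardize a zero-SD subject map", call. = FALSE)
    }
    maps[[which]] <- (m - mu) / sd
  }
  maps$standardized <- TRUE
  maps
}

#' Remove group-by-cohort cell means from subject maps
#'
#' Subtracts from each subject's map the voxelwise mean map of its group
#' x cohort cell, leaving every cell with mean zero while preserving
#' within-cell variance (the mean-controlled analysis variant).
#'
#' @param maps a `conn_map_set`; every group x cohort cell needs >= 2
#'   subjects.
#' @return the demeaned `conn_map_set`.
#' @export
demean_by_subgroup <- function(maps) {
  p <- maps$participants
  cell <- interaction(p$group, p$cohort, drop = TRUE)
  if (any(table(cell) < 2)) {
    stop("every group x cohort cell needs >= 2 subjects", call. = FALSE)
  }
  for (which in c("t", "beta")) {
    m <- maps[[which]]
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      m[idx, ] <- sweep(m[idx, , drop = FALSE], 2, colMeans(m[idx, , drop = FALSE]))
    }
    maps[[which]] <- m
  }
  maps$demeaned <- TRUE
  maps
}
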