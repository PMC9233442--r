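#' Subset a map set by subjects
#'
#' @param maps a `conn_map_set`.
#' @param idx logical/integer subject index, or character subject ids.
#' @return the subsetted `conn_map_set`.
#' @export
subset_maps <- function(maps, idx) {
  if (is.character(idx)) idx <- match(idx, maps$participants$subject_id)
  maps$t <- maps$t[idx, , drop = FALSE]
  maps$beta <- maps$beta[idx, , drop = FALSE]
  maps$participants <- maps$participants[idx, , drop = FALSE]
  maps
}

#' Per-subject parcel connectivity profiles
#'
#' Averages each subject's connectivity map within every parcel of the
#' parcellation, producing the subjects x parcels fingerprint matrix used
#' for clustering.  Designated labels (typically the seed's own area and
#' its neighbours) are excluded; parcels empty within the analysis mask
#' are dropped with a warning.
#'
#' @param maps a `conn_map_set`.
#' @param parcellation integer 3D array, or a `varconn_atlas`.
#' @param excluded_labels integer labels to leave out.
#' @param stat `"t"` or `"beta"` (defaults to the set's choice).
#' @return numeric matrix, subjects x parcels, columns named
#'   `parcel_<label>` in sorted label order.
#' @export
parcel_profiles <- function(maps, parcellation, excluded_labels = integer(0),
                            stat = NULL) {
  if (inherits(parcellation, "varconn_atlas")) {
    parcellation <- parcellation$parcellation
  }
  labs_in_mask <- parcellation[maps$mask]
  keep <- sort(setdiff(unique(labs_in_mask[labs_in_mask > 0]), excluded_labels))
  all_labels <- sort(setdiff(unique(parcellation[parcellation > 0]), excluded_labels))
  dropped <- setdiff(all_labels, keep)
  if (length(dropped)) {
    warning(
      "parcel(s) empty within the mask, dropped: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  v <- map_values(maps, stat)
  out <- vapply(
    keep,
    function(l) rowMeans(v[, labs_in_mask == l, drop = FALSE]),
    numeric(nrow(v))
  )
  out <- matrix(out,
    nrow = nrow(v),
    dimnames = list(
      maps$participants$subject_id, paste0("parcel_", keep)
    )
  )
  out
}

#' Hierarchical clustering of connectivity fingerprints
#'
#' Pairwise dissimilarity is the correlation distance `1 - Pearson r`
#' between subjects' parcel profiles; subjects are agglomerated by
#' complete linkage.  The result is deterministic given the input order.
#'
#' @param profiles subjects x parcels matrix from [parcel_profiles()]
#'   (>= 3 subjects, no zero-variance rows).
#' @return an object of class `dendrogram_result`: `dissimilarity`
#'   (full symmetric matrix), `linkage` (an `hclust` object),
#'   `subject_order` (dendrogram leaf order).
#' @seealso [cut_clades()]
#' @export
hierarchical_cluster <- function(profiles) {
  stopifnot(nrow(profiles) >= 3)
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance profile for subject(s): ",
      paste(rownames(profiles)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  D <- 1 - stats::cor(t(profiles))
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  structure(
    list(
      dissimilarity = D,
      linkage = hc,
      subject_order = rownames(profiles)[hc$order]
    ),
    class = "dendrogram_result"
  )
}

#' Cut a fingerprint dendrogram into clades
#'
#' @param dres a [hierarchical_cluster()] result.
#' @param k number of clades.
#' @return integer clade labels named by subject.
#' @export
cut_clades <- function(dres, k) {
  stats::cutree(dres$linkage, k = k)
}

#' Mean connectivity map per clade
#'
#' Voxelwise arithmetic mean of the member subjects' maps for each clade.
#'
#' @param maps a `conn_map_set`.
#' @param clade_assignment integer labels named by subject id (e.g. from
#'   [cut_clades()]); every clade must be nonempty.
#' @param stat `"t"` or `"beta"`.
#' @return named list of 3D arrays, one per clade.
#' @export
clade_mean_maps <- function(maps, clade_assignment, stat = NULL) {
  v <- map_values(maps, stat)
  ids <- maps$participants$subject_id
  stopifnot(all(names(clade_assignment) %in% ids))
  out <- list()
  for (cl in sort(unique(clade_assignment))) {
    members <- match(names(clade_assignment)[clade_assignment == cl], ids)
    out[[paste0("clade_", cl)]] <- vol_from_masked(
      colMeans(v[members, , drop = FALSE]), maps$mask
    )
  }
  out
}

#' Compare fingerprint dissimilarity between groups
#'
#' Tests whether one group's subjects are mutually more dissimilar than
#' the other's.  The primary scheme averages, per subject, the distance
#' to all own-group members and compares those per-subject means between
#' groups with a pooled two-sample t (`df = n_b + n_s - 2`), avoiding the
#' non-independence of pairwise entries.  A naive scheme -- a t test on
#' the pooled lower-triangle entries themselves -- is also returned,
#' flagged for its non-independent observations.
#'
#' @param dissimilarity_blind,dissimilarity_sighted symmetric
#'   within-group dissimilarity matrices (>= 3 subjects each).
#' @return list with `primary` and `naive` (each `t`, `df`, `p`), signed
#'   blind minus sighted, and the per-group mean distances.
#' @export
compare_group_distances <- function(dissimilarity_blind,
                                    dissimilarity_sighted) {
  check <- function(D, who) {
    if (nrow(D) < 3) stop(who, " group needs >= 3 subjects", call. = FALSE)
    if (max(abs(D - t(D))) > 1e-8) {
      stop(who, " dissimilarity matrix is not symmetric", call. = FALSE)
    }
  }
  check(dissimilarity_blind, "blind")
  check(dissimilarity_sighted, "sighted")
  per_subject <- function(D) {
    n <- nrow(D)
    (rowSums(D) - diag(D)) / (n - 1)
  }
  pooled_t <- function(x, y) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value
    )
  }
  mb <- per_subject(dissimilarity_blind)
  ms <- per_subject(dissimilarity_sighted)
  lb <- dissimilarity_blind[lower.tri(dissimilarity_blind)]
  ls <- dissimilarity_sighted[lower.tri(dissimilarity_sighted)]
  naive <- pooled_t(lb, ls)
  naive$caveat <- "pairwise distances are not independent observations"
  list(
    primary = pooled_t(mb, ms),
    naive = naive,
    mean_distance_blind = mean(lb),
    mean_distance_sighted = mean(ls)
  )
}

#' Voxelwise covariate correlation with cluster-extent correction
#'
#' Pearson correlation between each voxel's connectivity value and a
#' subject-level covariate (e.g. years of education), within one group or
#' across all subjects.  Significance is assessed by the t transform of r
#' and, optionally, cluster-extent corrected: smoothness is estimated from
#' the correlation map and the minimum extent derived by
#' [monte_carlo_min_cluster()].
#'
#' @param maps a `conn_map_set`.
#' @param covariate numeric vector aligned with the map set's
#'   participants, or the name of a participants column.
#' @param group optional `"blind"`/`"sighted"` filter.
#' @param stat `"t"` or `"beta"`.
#' @param correct apply cluster-extent correction.
#' @param voxel_p,alpha,n_iter,rng_seed correction parameters.
#' @return list with 3D arrays `r` and `p`, `n`, `df`, and (when
#'   corrected) `clusters` (a [threshold_and_label()] result) and
#'   `threshold` (the `cluster_threshold`).
#' @export
covariate_correlation <- function(maps, covariate, group = NULL, stat = NULL,
                                  correct = TRUE, voxel_p = 0.005,
                                  alpha = 0.05, n_iter = 1000,
                                  rng_seed = NULL) {
  p <- maps$participants
  if (is.character(covariate) && length(covariate) == 1L) {
    covariate <- p[[covariate]]
  }
  stopifnot(length(covariate) == nrow(p))
  keep <- if (is.null(group)) rep(TRUE, nrow(p)) else p$group == group
  cv <- covariate[keep]
  n <- sum(keep)
  if (n < 5) stop("need >= 5 subjects", call. = FALSE)
  if (!all(is.finite(cv))) stop("covariate must be finite", call. = FALSE)
  if (stats::sd(cv) == 0) stop("covariate is constant", call. = FALSE)
  v <- map_values(maps, stat)[keep, , drop = FALSE]
  r <- as.vector(stats::cor(cv, v))
  df <- n - 2L
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- list(
    r = vol_from_masked(r, maps$mask),
    p = vol_from_masked(pval, maps$mask),
    n = n, df = df
  )
  if (correct) {
    fwhm <- tryCatch(
      estimate_smoothness(out$r, maps$mask, maps$voxel_size_mm),
      error = function(e) maps$voxel_size_mm
    )
    thr <- monte_carlo_min_cluster(
      maps$mask, fwhm,
      voxel_p = voxel_p, alpha = alpha,
      n_iter = n_iter, rng_seed = rng_seed,
      voxel_size_mm = maps$voxel_size_mm
    )
    tmap <- vol_from_masked(tval, maps$mask)
    out$clusters <- threshold_and_label(
      tmap,
      min_cluster_size = thr$min_cluster_size_voxels,
      voxel_p = voxel_p, df = df, stat_kind = "t", mask = maps$mask
    )
    out$threshold <- thr
  }
  out
}

#' ROI covariate correlation
#'
#' Correlates each subject's mean map value over an ROI with a covariate
#' (Pearson, two-sided p).
#'
#' @inheritParams covariate_correlation
#' @param roi_mask logical 3D array.
#' @return list with `r`, `p`, `n`.
#' @export
roi_covariate_correlation <- function(maps, roi_mask, covariate,
                                      group = NULL, stat = NULL) {
  p <- maps$participants
  if (is.character(covariate) && length(covariate) == 1L) {
    covariate <- p[[covariate]]
  }
  keep <- if (is.null(group)) rep(TRUE, nrow(p)) else p$group == group
  in_roi <- roi_mask[maps$mask]
  if (!any(in_roi)) stop("ROI is empty within the analysis mask", call. = FALSE)
  vals <- rowMeans(map_values(maps, stat)[keep, in_roi, drop = FALSE])
  ct <- stats::cor.test(covariate[keep], vals)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
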