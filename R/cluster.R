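#' Estimate spatial smoothness (FWHM) of statistic maps
#'
#' Classic first-difference variance-ratio estimator: along each axis the
#' lag-one autocorrelation of in-mask voxel pairs is derived from
#' `var(diff) = 2 var (1 - rho)`, converted to the FWHM of the Gaussian
#' kernel that would give white noise that autocorrelation, and the three
#' axis FWHMs are combined by their geometric mean.  With several maps the
#' per-map estimates are averaged.
#'
#' @param maps a 3D array, a list of 3D arrays, or a `conn_map_set`.
#' @param mask logical 3D array (defaults to the map set's mask).
#' @param voxel_size_mm voxel size in mm.
#' @return estimated FWHM in mm.  Maps with near-zero neighbour
#'   correlation return the voxel-size floor with a warning; a constant
#'   map is an error.
#' @export
estimate_smoothness <- function(maps, mask = NULL, voxel_size_mm = 3) {
  if (inherits(maps, "conn_map_set")) {
    mask <- maps$mask
    voxel_size_mm <- maps$voxel_size_mm
    v <- maps[[maps$stat]]
    maps <- lapply(seq_len(nrow(v)), function(i) vol_from_masked(v[i, ], mask))
  }
  if (is.array(maps) && length(dim(maps)) == 3L) maps <- list(maps)
  stopifnot(length(maps) >= 1)
  if (is.null(mask)) mask <- array(TRUE, dim(maps[[1]]))
  d <- dim(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  pair_idx <- lapply(1:3, function(ax) {
    keep <- slice.index(array(TRUE, d), ax) < d[ax]
    a <- which(mask & keep)
    a[mask[a + strides[ax]]]
  })
  one_map <- function(m) {
    vals <- m[mask]
    v <- stats::var(vals)
    if (!is.finite(v) || v == 0) {
      stop("cannot estimate smoothness of a constant map", call. = FALSE)
    }
    fwhm_ax <- vapply(1:3, function(ax) {
      a <- pair_idx[[ax]]
      vd <- stats::var(m[a + strides[ax]] - m[a])
      rho <- 1 - vd / (2 * v)
      if (!is.finite(rho) || rho <= 0) {
        return(NA_real_)
      }
      sigma_to_fwhm(sqrt(-1 / (4 * log(rho)))) * voxel_size_mm
    }, numeric(1))
    if (anyNA(fwhm_ax)) {
      warning(
        "near-zero neighbour correlation; returning the voxel-size floor",
        call. = FALSE
      )
      fwhm_ax[is.na(fwhm_ax)] <- voxel_size_mm
    }
    exp(mean(log(pmax(fwhm_ax, voxel_size_mm * 0.1))))
  }
  mean(vapply(maps, one_map, numeric(1)))
}

#' Monte Carlo minimum cluster extent
#'
#' Simulates null statistic volumes (white Gaussian noise smoothed to the
#' supplied FWHM, z-scored within the mask), thresholds them two-sided at
#' the voxel-level p, records the largest face-connected cluster per
#' iteration (per sign), and returns the smallest cluster size `k` whose
#' exceedance probability is at most `alpha` -- the minimum extent a real
#' cluster must reach to be called significant family-wise.
#'
#' @param mask logical 3D array (the correction volume, e.g. gray matter).
#' @param fwhm_mm assumed map smoothness (from [estimate_smoothness()]).
#' @param voxel_p cluster-forming two-sided voxel p threshold.
#' @param alpha family-wise alpha.
#' @param n_iter Monte Carlo iterations (10,000 for production; tests may
#'   use fewer).
#' @param rng_seed integer seed; the threshold is deterministic given it.
#' @param voxel_size_mm voxel size in mm.
#' @return an object of class `cluster_threshold`: the inputs plus
#'   `min_cluster_size_voxels` and the simulated `max_cluster_sizes`.
#' @export
monte_carlo_min_cluster <- function(mask, fwhm_mm, voxel_p = 0.005,
                                    alpha = 0.05, n_iter = 1000,
                                    rng_seed = NULL, voxel_size_mm = 3) {
  stopifnot(any(mask), voxel_p > 0, voxel_p < 1)
  if (alpha < 1 / n_iter) {
    stop(sprintf(
      "alpha = %g is below the resolution 1/n_iter = %g; increase n_iter",
      alpha, 1 / n_iter
    ), call. = FALSE)
  }
  d <- dim(mask)
  zcrit <- stats::qnorm(1 - voxel_p / 2)
  in_mask <- which(mask)
  max_sizes <- integer(n_iter)
  with_seed(rng_seed, {
    chunk <- max(1L, min(n_iter, floor(2e7 / prod(d))))
    done <- 0L
    while (done < n_iter) {
      nb <- min(chunk, n_iter - done)
      vols <- array(stats::rnorm(prod(d) * nb), dim = c(d, nb))
      if (fwhm_mm > 0) {
        vols <- smooth_volume(vols, fwhm_mm, voxel_size_mm)
      }
      for (b in seq_len(nb)) {
        v <- vols[, , , b]
        x <- v[in_mask]
        z <- (x - mean(x)) / stats::sd(x)
        flag <- array(FALSE, d)
        flag[in_mask] <- z > zcrit
        mx <- max_cluster_size(flag)
        flag[in_mask] <- z < -zcrit
        max_sizes[done + b] <- max(mx, max_cluster_size(flag))
      }
      done <- done + nb
    }
  })
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(
    list(
      voxel_p = voxel_p, alpha = alpha, estimated_fwhm_mm = fwhm_mm,
      min_cluster_size_voxels = k, n_iterations = as.integer(n_iter),
      rng_seed = rng_seed, max_cluster_sizes = max_sizes
    ),
    class = "cluster_threshold"
  )
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(
    "cluster threshold: >= %d voxels (voxel p %g two-sided, alpha %g, fwhm %.2f mm, %d iterations)\n",
    x$min_cluster_size_voxels, x$voxel_p, x$alpha,
    x$estimated_fwhm_mm, x$n_iterations
  ))
  invisible(x)
}

# Convert a voxel-level p threshold to a statistic threshold.
stat_threshold_value <- function(voxel_p, stat_kind = c("t", "z", "F"),
                                 df = NULL) {
  stat_kind <- match.arg(stat_kind)
  switch(stat_kind,
    t = stats::qt(1 - voxel_p / 2, df[1]),
    z = stats::qnorm(1 - voxel_p / 2),
    F = stats::qf(1 - voxel_p, df[1], df[2])
  )
}

#' Threshold a statistic map and label surviving clusters
#'
#' Applies a voxel-level threshold (given directly, or derived from a p
#' value and the statistic's degrees of freedom), forms face-connected
#' clusters separately for positive and negative suprathreshold voxels,
#' discards clusters smaller than the minimum extent, and tabulates the
#' survivors.
#'
#' @param stat_map 3D statistic array.
#' @param min_cluster_size minimum surviving cluster extent in voxels
#'   (e.g. from [monte_carlo_min_cluster()]).
#' @param stat_threshold voxel threshold on the statistic scale; computed
#'   from `voxel_p`/`df`/`stat_kind` when omitted.
#' @param voxel_p,df,stat_kind alternative threshold specification: a
#'   two-sided p for `"t"`/`"z"` maps or an upper-tail p for `"F"` maps
#'   (F maps form positive clusters only).
#' @param mask optional logical 3D array restricting the search.
#' @return list with `labels` (integer 3D array, 0 = background) and
#'   `table` (data frame: cluster, sign, size_voxels, peak value and
#'   peak voxel indices), plus the threshold used.
#' @export
threshold_and_label <- function(stat_map, min_cluster_size = 1L,
                                stat_threshold = NULL, voxel_p = NULL,
                                df = NULL, stat_kind = "t", mask = NULL) {
  if (is.null(stat_threshold)) {
    if (is.null(voxel_p)) {
      stop("supply stat_threshold or voxel_p (with df/stat_kind)",
        call. = FALSE
      )
    }
    stat_threshold <- stat_threshold_value(voxel_p, stat_kind, df)
  }
  d <- dim(stat_map)
  ok <- is.finite(stat_map)
  if (!is.null(mask)) ok <- ok & mask
  signs <- if (identical(stat_kind, "F")) 1 else c(1, -1)
  labels <- array(0L, dim = d)
  rows <- list()
  next_id <- 0L
  for (sg in signs) {
    flag <- ok & (sg * stat_map > stat_threshold)
    lab <- label_components(flag)
    if (!any(lab > 0L)) next
    sizes <- tabulate(lab[lab > 0L])
    for (cl in which(sizes >= min_cluster_size)) {
      next_id <- next_id + 1L
      idx <- which(lab == cl)
      peak <- idx[which.max(sg * stat_map[idx])]
      pk <- arrayInd(peak, d)
      labels[idx] <- next_id
      rows[[next_id]] <- data.frame(
        cluster = next_id, sign = sg, size_voxels = sizes[cl],
        peak_value = stat_map[peak],
        peak_i = pk[1], peak_j = pk[2], peak_k = pk[3]
      )
    }
  }
  list(
    labels = labels,
    table = if (length(rows)) {
      do.call(rbind, rows)
    } else {
      data.frame(
        cluster = integer(0), sign = numeric(0), size_voxels = integer(0),
        peak_value = numeric(0), peak_i = integer(0), peak_j = integer(0),
        peak_k = integer(0)
      )
    },
    stat_threshold = stat_threshold,
    min_cluster_size = as.integer(min_cluster_size)
  )
}
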