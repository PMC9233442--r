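#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments.  Unlike the Pearson correlation, the CCC
#' penalizes mean and scale differences between the two value sets, so it
#' measures agreement, not just shared fluctuation; `|CCC| <= |r|` always,
#' with equality iff means and variances match.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return the CCC in `[-1, 1]`; NaN (with a warning) when both inputs
#'   have zero variance.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  vx <- mean(x^2) - mx^2
  vy <- mean(y^2) - my^2
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    warning("both inputs have zero variance and equal means; CCC undefined",
      call. = FALSE
    )
    return(NaN)
  }
  2 * (mean(x * y) - mx * my) / denom
}

#' Fisher z transform of a correlation
#'
#' `atanh(r)`, with `|r| >= 1` clipped to `1 - 1e-12` (warned) so the
#' transform stays finite.
#'
#' @param r correlation value(s).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  clip <- abs(r) >= 1
  if (any(clip, na.rm = TRUE)) {
    warning("|r| = 1 clipped to 1 - 1e-12 before atanh", call. = FALSE)
    r[clip] <- sign(r[clip]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Spatial-autocorrelation-preserving permutation test for map concordance
#'
#' Tests the CCC between two statistic maps against a null that keeps the
#' first map's value distribution *and* spatial smoothness: each iteration
#' shuffles map X's in-mask values uniformly at random, convolves the
#' shuffled volume with a Gaussian kernel whose FWHM equals the estimated
#' smoothness of the original map X, rescales the result to the original
#' in-mask mean and SD (smoothing shrinks variance; without rescaling the
#' null CCC is biased toward 0), and recomputes the CCC against map Y.
#' The p value is two-sided with the add-one correction,
#' `p = (1 + #\{|null| >= |observed|\}) / (n_iter + 1)`.
#'
#' @param map_x,map_y 3D statistic arrays on a shared grid; `map_x` is the
#'   map that gets shuffled.
#' @param mask logical 3D array (a warning is issued below 100 voxels).
#' @param n_iter permutation iterations (100,000 for production runs;
#'   10,000 is a reasonable desk default).
#' @param rng_seed integer seed.
#' @param fwhm_mm null-map smoothness; estimated from `map_x` when NULL.
#'   If smoothness estimation fails the test falls back to unsmoothed
#'   permutation and flags it.
#' @param voxel_size_mm voxel size in mm.
#' @return an object of class `ccc_result`: observed `ccc`, `p_value`,
#'   `n_iterations`, `null_mean`, `null_sd`, `null_ccc` (all iterations),
#'   `matched_fwhm_mm`, `smoothing_failed`, `rng_seed`.
#' @export
spatial_permutation_test <- function(map_x, map_y, mask, n_iter = 10000,
                                     rng_seed = NULL, fwhm_mm = NULL,
                                     voxel_size_mm = 3) {
  stopifnot(identical(dim(map_x), dim(map_y)), n_iter >= 100)
  nm <- sum(mask)
  if (nm < 100) {
    warning("mask has fewer than 100 voxels; permutation null is coarse",
      call. = FALSE
    )
  }
  x0 <- map_x[mask]
  y0 <- map_y[mask]
  observed <- lin_ccc(x0, y0)
  smoothing_failed <- FALSE
  if (is.null(fwhm_mm)) {
    fwhm_mm <- tryCatch(
      estimate_smoothness(map_x, mask, voxel_size_mm),
      error = function(e) NA_real_, warning = function(w) NA_real_
    )
    if (!is.finite(fwhm_mm)) {
      smoothing_failed <- TRUE
      fwhm_mm <- 0
    }
  }
  d <- dim(mask)
  in_mask <- which(mask)
  mu0 <- mean(x0)
  sd0 <- sqrt(mean(x0^2) - mu0^2)
  my <- mean(y0)
  vy <- mean(y0^2) - my^2
  w <- if (fwhm_mm > 0) {
    smooth_volume(array(as.numeric(mask), d), fwhm_mm, voxel_size_mm)[in_mask]
  } else {
    NULL
  }
  null_ccc <- numeric(n_iter)
  with_seed(rng_seed, {
    chunk <- max(1L, min(n_iter, floor(2e7 / prod(d))))
    done <- 0L
    while (done < n_iter) {
      nb <- min(chunk, n_iter - done)
      perm <- matrix(0, nm, nb)
      for (b in seq_len(nb)) perm[, b] <- x0[sample.int(nm)]
      if (fwhm_mm > 0) {
        vols <- array(0, dim = c(d, nb))
        flat <- matrix(vols, prod(d), nb)
        flat[in_mask, ] <- perm
        vols <- array(flat, dim = c(d, nb))
        vols <- smooth_volume(vols, fwhm_mm, voxel_size_mm)
        perm <- matrix(vols, prod(d), nb)[in_mask, , drop = FALSE] / w
      }
      mu <- colMeans(perm)
      sdv <- sqrt(colMeans(perm^2) - mu^2)
      # rescale each null map to the original in-mask mean and SD
      perm <- sweep(sweep(perm, 2, mu), 2, sdv / sd0, "/") + mu0
      mx <- colMeans(perm)
      vx <- colMeans(perm^2) - mx^2
      cv <- colMeans(perm * y0) - mx * my
      null_ccc[done + seq_len(nb)] <- 2 * cv / (vx + vy + (mx - my)^2)
      done <- done + nb
    }
  })
  structure(
    list(
      ccc = observed,
      p_value = (1 + sum(abs(null_ccc) >= abs(observed))) / (n_iter + 1),
      n_iterations = as.integer(n_iter),
      null_mean = mean(null_ccc), null_sd = stats::sd(null_ccc),
      null_ccc = null_ccc,
      matched_fwhm_mm = fwhm_mm, smoothing_failed = smoothing_failed,
      rng_seed = rng_seed
    ),
    class = "ccc_result"
  )
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf(
    "CCC = %.4f, permutation p = %.3g (%d iterations, null %.4f +/- %.4f, matched FWHM %.2f mm%s)\n",
    x$ccc, x$p_value, x$n_iterations, x$null_mean, x$null_sd,
    x$matched_fwhm_mm,
    if (x$smoothing_failed) ", smoothness estimation failed" else ""
  ))
  invisible(x)
}

#' Cross-seed specificity of the variability/reorganization concordance
#'
#' For every pair (variability map of seed i, group-difference map of seed
#' j) computes the CCC within the mask.  The diagonal holds the coupled
#' same-seed comparisons; off-diagonal entries are the cross-seed
#' controls.  After Fisher z transformation, the designated seed's
#' same-seed value is compared against (a) the distribution of cross-seed
#' values and (b) the other seeds' same-seed values, by one-sample t tests
#' (positive t means the designated seed exceeds the comparison set).
#' Optionally attaches a spatial permutation p for the designated seed's
#' same-seed CCC.
#'
#' @param variability_maps,groupdiff_maps named lists of 3D arrays, same
#'   seed names in the same order (>= 3 seeds).
#' @param mask logical 3D array.
#' @param designated_seed name or index of the seed of interest.
#' @param n_iter if > 0, permutation iterations for the designated
#'   same-seed CCC (see [spatial_permutation_test()]).
#' @param rng_seed seed for the permutation test.
#' @param voxel_size_mm voxel size in mm.
#' @return an object of class `seed_specificity`: `ccc_matrix`,
#'   `same_seed_ccc`, `fisher_z` matrix, the two t comparisons
#'   (`t_vs_cross`, `t_vs_other_same`, each with `t`, `df`, `p`), and
#'   optionally `designated_permutation` (a `ccc_result`).
#' @export
cross_seed_specificity <- function(variability_maps, groupdiff_maps, mask,
                                   designated_seed = 1, n_iter = 0,
                                   rng_seed = NULL, voxel_size_mm = 3) {
  k <- length(variability_maps)
  stopifnot(k >= 3, length(groupdiff_maps) == k)
  seeds <- names(variability_maps)
  if (is.null(seeds)) {
    seeds <- as.character(seq_len(k))
    names(variability_maps) <- names(groupdiff_maps) <- seeds
  }
  stopifnot(identical(seeds, names(groupdiff_maps)))
  if (is.numeric(designated_seed)) designated_seed <- seeds[designated_seed]
  ccc <- matrix(NA_real_, k, k, dimnames = list(seeds, seeds))
  for (i in seq_len(k)) {
    vi <- variability_maps[[i]][mask]
    for (j in seq_len(k)) {
      ccc[i, j] <- lin_ccc(vi, groupdiff_maps[[j]][mask])
    }
  }
  z <- fisher_z(ccc)
  di <- match(designated_seed, seeds)
  z_des <- z[di, di]
  cross <- z[row(z) != col(z)]
  other_same <- diag(z)[-di]
  one_sample <- function(vals, mu) {
    tt <- stats::t.test(vals, mu = mu)
    list(
      t = -unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value
    )
  }
  out <- list(
    ccc_matrix = ccc, same_seed_ccc = diag(ccc), fisher_z = z,
    designated_seed = designated_seed,
    t_vs_cross = one_sample(cross, z_des),
    t_vs_other_same = one_sample(other_same, z_des)
  )
  if (n_iter > 0) {
    out$designated_permutation <- spatial_permutation_test(
      variability_maps[[di]], groupdiff_maps[[di]], mask,
      n_iter = n_iter, rng_seed = rng_seed, voxel_size_mm = voxel_size_mm
    )
  }
  structure(out, class = "seed_specificity")
}
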