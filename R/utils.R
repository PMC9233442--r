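# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a series with zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

# 1D Gaussian kernel in voxel units, truncated at 4 sigma, sum 1.
gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable convolution over the three leading (spatial) axes of a 3D or
# 4D array: multiply along the first axis, rotate the spatial axes, three
# times, which restores the original layout with a single aperm per axis.
conv_spatial <- function(arr, Ks) {
  four_d <- length(dim(arr)) == 4L
  a <- arr
  for (ax in 1:3) {
    da <- dim(a)
    dim(a) <- c(da[1], prod(da[-1]))
    a <- Ks[[ax]] %*% a
    dim(a) <- da
    a <- aperm(a, if (four_d) c(2, 3, 1, 4) else c(2, 3, 1))
  }
  a
}

# Kernel matrix for one axis: row i holds the kernel centred at i,
# truncated at the volume edge (no renormalization; callers that need
# unbiased borders divide by the smoothed mask).
kernel_matrix <- function(d, sigma_vox) {
  k <- gaussian_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- max(1L, i - r):min(d, i + r)
    K[i, j] <- k[j - i + r + 1L]
  }
  K
}

#' Gaussian-smooth a 3D volume (or a stack of volumes)
#'
#' Separable Gaussian convolution over the three spatial axes, in mm units.
#' When `mask` is supplied, values outside the mask are ignored and in-mask
#' values are renormalized by the smoothed mask so border voxels are
#' unbiased.
#'
#' @param vol 3D array, or 4D array whose 4th axis indexes volumes.
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is identity.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param mask optional logical 3D array; smoothing is restricted to it.
#' @return array of the same shape as `vol`.
#' @keywords internal
smooth_volume <- function(vol, fwhm_mm, voxel_size_mm, mask = NULL) {
  if (fwhm_mm <= 0) {
    return(vol)
  }
  sigma <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  d <- dim(vol)
  Ks <- lapply(d[1:3], kernel_matrix, sigma_vox = sigma)
  if (is.null(mask)) {
    return(conv_spatial(vol, Ks))
  }
  w <- conv_spatial(array(as.numeric(mask), dim = d[1:3]), Ks)
  if (length(d) == 3L) {
    v <- vol
    v[!mask] <- 0
    out <- conv_spatial(v, Ks) / w
    out[!mask] <- vol[!mask]
    return(out)
  }
  out <- vol
  for (t in seq_len(d[4])) {
    v <- vol[, , , t]
    v[!mask] <- 0
    o <- conv_spatial(v, Ks) / w
    o[!mask] <- vol[, , , t][!mask]
    out[, , , t] <- o
  }
  out
}

# Face-adjacency (6-neighbour) connected components of a logical 3D array.
# Returns an integer array: 0 outside, component id (1..k) inside.
label_components <- function(flag) {
  d <- dim(flag)
  ids <- which(flag)
  lab <- array(0L, dim = d)
  if (length(ids) == 0L) {
    return(lab)
  }
  pos <- integer(prod(d))
  pos[ids] <- seq_along(ids)
  edge_a <- integer(0)
  edge_b <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    keep <- slice.index(array(TRUE, d), ax) < d[ax]
    both <- which(flag & keep)
    both <- both[flag[both + strides[ax]]]
    edge_a <- c(edge_a, pos[both])
    edge_b <- c(edge_b, pos[both + strides[ax]])
  }
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edge_a)) {
    for (e in seq_along(edge_a)) {
      ra <- find(edge_a[e])
      rb <- find(edge_b[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  lab[ids] <- match(roots, unique(roots))
  lab
}

# Size of the largest face-connected component of a logical 3D array.
max_cluster_size <- function(flag) {
  lab <- label_components(flag)
  if (!any(lab > 0L)) {
    return(0L)
  }
  max(tabulate(lab[lab > 0L]))
}

# Rebuild a 3D volume from in-mask values (NA outside the mask).
vol_from_masked <- function(values, mask) {
  out <- array(NA_real_, dim = dim(mask))
  out[mask] <- values
  out
}
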