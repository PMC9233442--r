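#' Build a synthetic parcellation with seed and tissue masks
#'
#' Constructs, on a common voxel grid, the label images a seed-RSFC study
#' needs: an integer parcellation of the gray matter into contiguous,
#' mutually exclusive parcels (the synthetic analogue of a Brodmann-style
#' atlas), a designated seed parcel, and white-matter and ventricle masks
#' disjoint from gray matter (used for nuisance regression).
#'
#' Tissue compartments occupy two corner blocks of the grid; the remaining
#' voxels are gray matter and are partitioned by multi-source region
#' growing from randomly placed parcel seeds, which guarantees contiguity.
#'
#' @param grid_shape integer vector of length 3, grid size in voxels.
#' @param n_parcels number of gray-matter parcels (>= 2).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param rng_seed integer seed controlling parcel-seed placement;
#'   identical inputs and seed give a byte-identical atlas.
#' @param seed_parcel which parcel label serves as the connectivity seed.
#' @return an object of class `varconn_atlas`: a list with integer array
#'   `parcellation` (0 outside gray matter, labels `1..n_parcels` inside),
#'   logical arrays `seed_mask`, `gray_mask`, `wm_mask`, `ventricle_mask`,
#'   and the grid metadata.
#' @export
make_atlas <- function(grid_shape, n_parcels, voxel_size_mm = 3,
                       rng_seed = NULL, seed_parcel = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L), n_parcels >= 2L)
  d <- grid_shape
  wm <- array(FALSE, d)
  vent <- array(FALSE, d)
  bx <- pmax(2L, d %/% 5L)
  wm[1:bx[1], 1:bx[2], 1:bx[3]] <- TRUE
  vent[(d[1] - bx[1] + 1L):d[1], 1:bx[2], 1:bx[3]] <- TRUE
  gray <- !(wm | vent)
  n_gray <- sum(gray)
  if (n_gray < 8L * n_parcels) {
    stop(sprintf(
      "grid too small: %d gray-matter voxels cannot hold %d parcels of >= 8 voxels",
      n_gray, n_parcels
    ), call. = FALSE)
  }
  with_seed(rng_seed, {
    parc <- NULL
    for (try in 1:25) {
      seeds <- spread_seeds(gray, n_parcels)
      cand <- grow_parcels(gray, seeds)
      if (min(tabulate(cand[cand > 0L], n_parcels)) >= 8L) {
        parc <- cand
        break
      }
    }
    if (is.null(parc)) {
      stop("could not place parcels with >= 8 voxels each; enlarge the grid",
        call. = FALSE
      )
    }
    structure(
      list(
        parcellation = parc,
        seed_mask = parc == as.integer(seed_parcel),
        gray_mask = gray,
        wm_mask = wm,
        ventricle_mask = vent,
        grid_shape = d,
        voxel_size_mm = voxel_size_mm,
        n_parcels = as.integer(n_parcels),
        seed_parcel = as.integer(seed_parcel)
      ),
      class = "varconn_atlas"
    )
  })
}

# Farthest-point (greedy k-center) placement of parcel seeds: the first
# seed is random, each further seed maximizes its distance to the chosen
# ones.  Yields well-separated seeds and hence parcels of comparable size.
spread_seeds <- function(gray, n_parcels) {
  idx <- which(gray)
  co <- arrayInd(idx, dim(gray))
  seeds <- integer(n_parcels)
  seeds[1] <- sample(length(idx), 1L)
  d2 <- colSums((t(co) - co[seeds[1], ])^2)
  for (k in seq_len(n_parcels - 1L)) {
    seeds[k + 1L] <- which.max(d2)
    d2 <- pmin(d2, colSums((t(co) - co[seeds[k + 1L], ])^2))
  }
  idx[seeds]
}

# Multi-source region growing over the gray mask, balanced: at each step
# the currently smallest parcel with room to grow claims one ring of
# unassigned face-neighbours, which keeps parcel sizes comparable.
# Deterministic given the seed voxels.
grow_parcels <- function(gray, seeds) {
  d <- dim(gray)
  n <- prod(d)
  ix <- ((seq_len(n) - 1L) %% d[1]) + 1L
  iy <- (((seq_len(n) - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((seq_len(n) - 1L) %/% (d[1] * d[2])) + 1L
  strides <- c(1L, d[1], d[1] * d[2])
  k <- length(seeds)
  lab <- integer(n)
  lab[seeds] <- seq_len(k)
  frontiers <- as.list(seeds)
  sizes <- rep(1L, k)
  active <- rep(TRUE, k)
  ring <- function(front) {
    cand <- integer(0)
    for (ax in 1:3) {
      co <- switch(ax, ix, iy, iz)
      cand <- c(
        cand,
        front[co[front] < d[ax]] + strides[ax],
        front[co[front] > 1L] - strides[ax]
      )
    }
    unique(cand[gray[cand] & lab[cand] == 0L])
  }
  while (any(active)) {
    p <- which(active)[which.min(sizes[active])]
    nb <- ring(frontiers[[p]])
    if (!length(nb)) {
      active[p] <- FALSE
      next
    }
    lab[nb] <- p
    sizes[p] <- sizes[p] + length(nb)
    frontiers[[p]] <- nb
  }
  array(lab, dim = d)
}

#' @export
print.varconn_atlas <- function(x, ...) {
  cat(sprintf(
    "varconn atlas: %s grid (%.1f mm voxels), %d parcels, seed = parcel %d\n",
    paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
    x$n_parcels, x$seed_parcel
  ))
  cat(sprintf(
    "  gray %d, white matter %d, ventricle %d voxels\n",
    sum(x$gray_mask), sum(x$wm_mask), sum(x$ventricle_mask)
  ))
  invisible(x)
}
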