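make_parcellation <- function(labels) {
  array(labels, dim = c(length(labels), 1, 1))
}

test_that("parcel profiles are per-parcel means with exclusions honoured", {
  # 6 voxels: parcels 1,1,2,2,3,3
  parc <- make_parcellation(c(1, 1, 2, 2, 3, 3))
  v <- rbind(
    c(1, 3, 5, 7, 9, 11),
    c(2, 2, 2, 2, 2, 2)
  )
  ms <- toy_map_set(v, group = c("blind", "blind"))
  prof <- parcel_profiles(ms, parc)
  expect_equal(unname(prof[1, ]), c(2, 6, 10))
  expect_equal(unname(prof[2, ]), c(2, 2, 2)) # constant map -> constant row
  ex <- parcel_profiles(ms, parc, excluded_labels = c(1, 3))
  expect_equal(colnames(ex), "parcel_2")
})

test_that("parcels empty within the mask are dropped with a warning", {
  parc <- make_parcellation(c(1, 1, 2, 2, 0, 0))
  v <- matrix(rnorm(12), 2, 6)
  ms <- toy_map_set(v, group = c("blind", "blind"))
  ms$mask[3:4] <- FALSE # parcel 2 now empty in-mask
  ms$t <- ms$t[, c(1, 2, 5, 6)]
  ms$beta <- ms$t
  expect_warning(prof <- parcel_profiles(ms, parc), "dropped: 2")
  expect_equal(colnames(prof), "parcel_1")
})

test_that("complete-linkage clustering matches brute-force agglomeration", {
  set.seed(14)
  profiles <- matrix(rnorm(4 * 10), 4,
    dimnames = list(paste0("s", 1:4), NULL)
  )
  res <- hierarchical_cluster(profiles)
  D <- 1 - cor(t(profiles))
  expect_equal(res$dissimilarity, D, tolerance = 1e-12)
  # brute-force complete linkage on 4 points
  clusters <- as.list(1:4)
  heights <- numeric(3)
  merges <- list()
  Dm <- D
  for (step in 1:3) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights[step] <- best_h
    merges[[step]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(res$linkage$height, heights, tolerance = 1e-12)
  # the two-member clade after the first merge matches
  first_pair <- merges[[1]]
  cl <- cut_clades(res, 3)
  expect_equal(cl[first_pair[1]], cl[first_pair[2]],
    ignore_attr = TRUE
  )
})

test_that("duplicated subjects merge first at height zero", {
  profiles <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 1, 9))
  res <- hierarchical_cluster(profiles)
  expect_equal(res$linkage$height[1], 0, tolerance = 1e-12)
  cl <- cut_clades(res, 2)
  expect_equal(cl[["a"]], cl[["b"]])
})

test_that("zero-variance profiles are rejected naming the subject", {
  profiles <- rbind(s1 = c(1, 2, 3), s2 = c(2, 2, 2), s3 = c(3, 1, 2))
  expect_error(hierarchical_cluster(profiles), "s2")
})

test_that("clustering is invariant to subject input order", {
  set.seed(15)
  profiles <- matrix(rnorm(8 * 12), 8,
    dimnames = list(paste0("s", 1:8), NULL)
  )
  cl1 <- cut_clades(hierarchical_cluster(profiles), 3)
  perm <- sample(8)
  cl2 <- cut_clades(hierarchical_cluster(profiles[perm, ]), 3)
  # same partition up to label renaming
  tab <- table(cl1[names(cl2)], cl2)
  expect_equal(sum(tab > 0), 3L)
})

test_that("dissimilarity is invariant to positive affine profile changes", {
  set.seed(16)
  profiles <- matrix(rnorm(5 * 9), 5,
    dimnames = list(paste0("s", 1:5), NULL)
  )
  d1 <- hierarchical_cluster(profiles)$dissimilarity
  profiles2 <- profiles
  profiles2[2, ] <- 4 * profiles[2, ] + 10
  d2 <- hierarchical_cluster(profiles2)$dissimilarity
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("clade mean maps average member maps", {
  v <- rbind(c(1, 2, 3), c(3, 4, 5), c(10, 10, 10))
  ms <- toy_map_set(v, group = rep("blind", 3))
  cl <- c(s01 = 1L, s02 = 1L, s03 = 2L)
  mm <- clade_mean_maps(ms, cl)
  expect_equal(as.vector(mm$clade_1[, 1, 1]), c(2, 3, 4))
  expect_equal(as.vector(mm$clade_2[, 1, 1]), c(10, 10, 10)) # singleton
})

test_that("group distance comparison detects scaled dissimilarity and flips sign", {
  set.seed(17)
  p <- matrix(rnorm(12 * 8), 12)
  D <- 1 - cor(t(p))
  out_null <- compare_group_distances(D[1:6, 1:6], D[7:12, 7:12])
  out_scaled <- compare_group_distances(1.5 * D[1:6, 1:6], D[7:12, 7:12])
  expect_gt(out_scaled$primary$t, out_null$primary$t)
  expect_gt(out_scaled$primary$t, 0)
  expect_equal(out_scaled$primary$df, 10)
  flipped <- compare_group_distances(D[7:12, 7:12], 1.5 * D[1:6, 1:6])
  expect_equal(flipped$primary$t, -out_scaled$primary$t, tolerance = 1e-10)
  expect_match(out_null$naive$caveat, "not independent")
  expect_error(compare_group_distances(D[1:2, 1:2], D[3:6, 3:6]), ">= 3")
})

test_that("a perfect linear covariate readout gives r = 1 at the voxel", {
  edu <- c(8, 10, 12, 14, 16, 18)
  v <- cbind(2 * edu - 5, rnorm(6))
  ms <- toy_map_set(v, group = rep("blind", 6))
  ms$participants$education_years <- edu
  out <- covariate_correlation(ms, "education_years", correct = FALSE)
  expect_equal(out$r[1, 1, 1], 1, tolerance = 1e-10)
  expect_lt(out$p[1, 1, 1], 1e-6)
  expect_error(
    covariate_correlation(ms, rep(3, 6), correct = FALSE),
    "constant"
  )
  roi <- array(c(TRUE, FALSE), dim = c(2, 1, 1))
  rr <- roi_covariate_correlation(ms, roi, "education_years")
  expect_equal(rr$r, 1, tolerance = 1e-10)
})
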