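test_that("bandpass removes DC and matches its own analytic response", {
  tr <- 2
  n <- 240
  t <- seq_len(n)
  # DC offset is outside the band
  expect_lt(abs(mean(bandpass(rep(5, n) + rnorm(n, sd = 0), tr))), 1e-10)
  # in-band sinusoid at 0.05 Hz preserved
  x <- sin(2 * pi * 0.05 * t * tr)
  y <- bandpass(x, tr)
  expect_gt(sd(y) / sd(x), 0.95)
  # out-of-band sinusoid at 0.2 Hz attenuated
  x2 <- sin(2 * pi * 0.2 * t * tr)
  expect_lt(sd(bandpass(x2, tr)) / sd(x2), 0.05)
  # frequency response from the impulse response equals the designed
  # raised-cosine transfer function
  imp <- c(1, rep(0, n - 1))
  H_emp <- Mod(fft(bandpass(imp, tr)))
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f)
  mid <- which(f > 0.03 & f < 0.08) # flat passband
  expect_true(all(abs(H_emp[mid] - 1) < 1e-8))
  stopband <- which(f > 0.12 | (f < 0.004 & f > 0))
  expect_true(all(H_emp[stopband] < 1e-8))
})

test_that("bandpass rejects bands invalid for the TR", {
  expect_error(bandpass(rnorm(100), tr = 6, high_hz = 0.1), "Nyquist")
  expect_error(bandpass(rnorm(100), tr = 2, low_hz = 0.2, high_hz = 0.1))
})

test_that("the matrix and per-column bandpass paths agree", {
  x <- matrix(rnorm(120 * 300), 120, 300) # wide: matrix-operator path
  direct <- bandpass(x, 2)
  per_col <- vapply(1:10, function(j) bandpass(x[, j], 2), numeric(120))
  expect_equal(direct[, 1:10], per_col, tolerance = 1e-10)
})

test_that("seed time course extraction z-scores the spatial mean", {
  bold <- array(rnorm(5 * 5 * 4 * 30), dim = c(5, 5, 4, 30))
  mask1 <- array(FALSE, c(5, 5, 4))
  mask1[2, 3, 1] <- TRUE
  ts <- extract_seed_timecourse(bold, mask1)
  expect_equal(ts, as.vector(scale(bold[2, 3, 1, ])), tolerance = 1e-12)
  expect_error(extract_seed_timecourse(bold, array(FALSE, c(5, 5, 4))), "empty")
  bold[] <- 1
  full <- array(TRUE, c(5, 5, 4))
  expect_error(extract_seed_timecourse(bold, full), "zero variance")
})

test_that("noise-free sessions return the generator's seed signal exactly", {
  study <- simulate_study(noisefree_spec())
  sess <- study$sessions[[1]]
  ts <- extract_seed_timecourse(sess, study$atlas$seed_mask)
  expect_equal(cor(ts, sess$seed_signal), 1, tolerance = 1e-9)
})

test_that("nuisance design has the documented columns", {
  study <- simulate_study(tiny_spec(seed = 3))
  sess <- study$sessions[[1]]
  a <- study$atlas
  X <- build_nuisance_design(sess, a$wm_mask, a$ventricle_mask)
  expect_equal(ncol(X), 15L)
  expect_equal(
    colnames(X),
    c(
      paste0("mot", 1:6), paste0("dmot", 1:6), "wm", "ventricle",
      "intercept"
    )
  )
  # non-intercept columns are z-scored
  expect_true(all(abs(colMeans(X[, 1:14])) < 1e-10))
  expect_true(all(abs(apply(X[, 1:14], 2, sd) - 1) < 1e-10))
  Xg <- build_nuisance_design(sess, a$wm_mask, a$ventricle_mask,
    use_global = TRUE
  )
  expect_equal(ncol(Xg), 16L)
  expect_true("global" %in% colnames(Xg))
})

test_that("zero motion gives zero derivative columns flagged as degenerate", {
  study <- simulate_study(tiny_spec(seed = 3))
  sess <- study$sessions[[1]]
  sess$motion[] <- 0
  a <- study$atlas
  # zero motion triggers both the degenerate-column and the
  # rank-deficiency warnings
  w <- capture_warnings(
    X <- build_nuisance_design(sess, a$wm_mask, a$ventricle_mask)
  )
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(X[, paste0("dmot", 1:6)] == 0))
  expect_true(all(paste0("dmot", 1:6) %in% attr(X, "degenerate_columns")))
})

test_that("the voxelwise GLM t matches explicit normal-equations algebra", {
  set.seed(7)
  nt <- 10
  seed_series <- as.vector(scale(rnorm(nt)))
  nuis <- cbind(intercept = 1, z = as.vector(scale(rnorm(nt))))
  bold <- array(rnorm(2 * 2 * 1 * nt), dim = c(2, 2, 1, nt))
  sess <- structure(
    list(
      bold = bold, tr = 2, motion = matrix(0, nt, 6),
      subject_id = "s", group = "blind", cohort = "A"
    ),
    class = "scan_session"
  )
  cm <- seed_glm_map(sess, seed_series, nuis)
  # oracle: per voxel, explicit OLS via solve(X'X) X'y on the z-scored series
  X <- cbind(seed_series, nuis)
  for (vox in 1:4) {
    y <- as.vector(scale(bold[arrayInd(vox, c(2, 2, 1))[1],
      arrayInd(vox, c(2, 2, 1))[2], 1, ]))
    XtXi <- solve(crossprod(X))
    beta <- XtXi %*% crossprod(X, y)
    res <- y - X %*% beta
    se <- sqrt(sum(res^2) / (nt - 3) * XtXi[1, 1])
    expect_equal(cm$t[vox], beta[1] / se, tolerance = 1e-10)
    expect_equal(cm$beta[vox], beta[1], tolerance = 1e-10)
  }
  expect_equal(cm$df, nt - 3L)
})

test_that("perfect and orthogonal predictors bound the GLM output", {
  nt <- 40
  s <- as.vector(scale(sin(seq_len(nt))))
  orth <- as.vector(scale(residuals(lm(rnorm(nt) ~ s))))
  bold <- array(0, dim = c(2, 1, 1, nt))
  bold[1, 1, 1, ] <- s
  bold[2, 1, 1, ] <- orth
  sess <- structure(
    list(bold = bold, tr = 2, motion = matrix(0, nt, 6), subject_id = "s"),
    class = "scan_session"
  )
  cm <- seed_glm_map(sess, s, matrix(1, nt, 1,
    dimnames = list(NULL, "intercept")
  ))
  expect_equal(cm$beta[1, 1, 1], 1, tolerance = 1e-9)
  expect_gt(cm$t[1, 1, 1], 1e6)
  expect_lt(abs(cm$beta[2, 1, 1]), 1e-9)
})

test_that("map smoothing is an identity at fwhm 0 and matches the requested width", {
  d <- c(21, 21, 21)
  img <- array(0, dim = d)
  img[11, 11, 11] <- 1
  expect_identical(smooth_map(img, 0), img)
  sm <- smooth_map(img, fwhm_mm = 6, voxel_size_mm = 3)
  # fit the impulse response: fwhm from the second moment along one axis
  prof <- sm[, 11, 11]
  x <- (1:21 - 11) * 3
  sigma <- sqrt(sum(prof * x^2) / sum(prof))
  expect_equal(sigma * 2 * sqrt(2 * log(2)), 6, tolerance = 0.05 * 6)
})

test_that("per-subject standardization is exact and affine invariant", {
  set.seed(1)
  v <- matrix(rnorm(6 * 50), 6, 50)
  ms <- toy_map_set(v, group = rep(c("blind", "sighted"), 3),
    cohort = rep(c("A", "B"), each = 3))
  std <- site_standardize(ms)
  expect_true(all(abs(rowMeans(std$t)) < 1e-9))
  expect_true(all(abs(apply(std$t, 1, sd) - 1) < 1e-9))
  # maps differing only by an affine site transform standardize identically
  ms2 <- ms
  ms2$t <- 2 * ms$t + 10
  ms2$beta <- ms2$t
  expect_equal(site_standardize(ms2)$t, std$t, tolerance = 1e-12)
})

test_that("cell demeaning zeroes cell means and preserves within-cell variance", {
  set.seed(2)
  v <- matrix(rnorm(8 * 40), 8, 40)
  grp <- rep(c("blind", "sighted"), each = 4)
  coh <- rep(c("A", "B"), 4)
  ms <- toy_map_set(v, group = grp, cohort = coh)
  dm <- demean_by_subgroup(ms)
  for (g in c("blind", "sighted")) {
    for (ch in c("A", "B")) {
      idx <- grp == g & coh == ch
      expect_true(all(abs(colMeans(dm$t[idx, ])) < 1e-9))
      expect_equal(
        apply(dm$t[idx, ], 2, var), apply(v[idx, ], 2, var),
        tolerance = 1e-12
      )
    }
  }
  ms_bad <- toy_map_set(v[1:5, ],
    group = c("blind", "blind", "blind", "blind", "sighted"),
    cohort = c("A", "A", "B", "B", "A")
  )
  expect_error(demean_by_subgroup(ms_bad), ">= 2 subjects")
})

test_that("the map pipeline is equivariant to subject order", {
  study <- simulate_study(tiny_spec(seed = 4))
  maps <- rsfc_maps(study, fwhm_mm = 4)
  perm <- c(4, 1, 12, 3, 7, 2, 9, 5, 11, 8, 6, 10)
  study2 <- study
  study2$sessions <- study$sessions[perm]
  study2$participants <- study$participants[perm, ]
  maps2 <- rsfc_maps(study2, fwhm_mm = 4)
  expect_equal(maps2$t, maps$t[perm, ], tolerance = 1e-10)
})

test_that("near-noise-free t maps recover the planted weight ranking", {
  # under a z-normalized GLM the beta saturates (beta = w/sqrt(w^2+s^2)
  # approaches +/-1 as noise vanishes), while the t statistic stays
  # proportional to the weight; rank recovery is therefore checked on t
  study <- simulate_study(noisefree_spec(
    seed = 6,
    noise_sd = 0.1, noise_fwhm_mm = 0,
    map_topography_sd = 0.5, # voxelwise-distinct true weights
    n_vols_by_cohort = c(A = 150, B = 200)
  ))
  maps <- rsfc_maps(study, fwhm_mm = 0)
  parc <- study$atlas$parcellation[maps$mask]
  w <- study$ground_truth$weight_by_subject_region
  topo <- study$ground_truth$topography
  for (i in c(1, 5, 9)) {
    w_vox <- w[i, parc] + topo[maps$mask]
    expect_gt(cor(maps$t[i, ], w_vox, method = "spearman"), 0.99)
    # the beta map agrees in sign/order up to its saturation plateau
    expect_gt(cor(maps$beta[i, ], w_vox, method = "spearman"), 0.7)
  }
})

test_that("global-signal and plain variants share a grid and both complete", {
  study <- simulate_study(tiny_spec(seed = 8))
  m0 <- rsfc_maps(study, fwhm_mm = 4)
  m1 <- rsfc_maps(study, fwhm_mm = 4, use_global = TRUE)
  expect_identical(dim(m0$t), dim(m1$t))
  expect_identical(m0$mask, m1$mask)
  expect_false(identical(m0$t, m1$t))
})
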