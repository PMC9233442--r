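test_that("the 2x2 ANOVA map matches a type-III car::Anova oracle", {
  skip_if_not_installed("car")
  set.seed(11)
  for (balanced in c(TRUE, FALSE)) {
    if (balanced) {
      grp <- rep(c("blind", "sighted"), each = 6)
      coh <- rep(rep(c("A", "B"), each = 3), 2)
    } else {
      grp <- c(rep("blind", 7), rep("sighted", 9))
      coh <- c(rep("A", 4), rep("B", 3), rep("A", 5), rep("B", 4))
    }
    v <- matrix(rnorm(length(grp) * 6), length(grp), 6)
    ms <- toy_map_set(v, group = grp, cohort = coh)
    an <- anova_2x2_map(ms)
    for (vox in 1:6) {
      fit <- lm(v[, vox] ~ g * co, data = data.frame(
        g = factor(grp), co = factor(coh)
      ), contrasts = list(g = contr.sum, co = contr.sum))
      oracle <- car::Anova(fit, type = 3)
      expect_equal(an$F_group[vox], oracle["g", "F value"], tolerance = 1e-8)
      expect_equal(an$F_cohort[vox], oracle["co", "F value"], tolerance = 1e-8)
      expect_equal(an$F_interaction[vox], oracle["g:co", "F value"],
        tolerance = 1e-8
      )
      expect_equal(an$p_group[vox], oracle["g", "Pr(>F)"], tolerance = 1e-8)
    }
    expect_equal(an$df, c(1L, length(grp) - 4L))
  }
})

test_that("identical maps across subjects give NaN F (zero residual)", {
  v <- matrix(rep(c(1, 2, 3, 4, 5), each = 8), 8, 5)
  ms <- toy_map_set(v,
    group = rep(c("blind", "sighted"), 4),
    cohort = rep(c("A", "B"), each = 4)
  )
  an <- anova_2x2_map(ms)
  expect_true(all(is.nan(an$F_group[, 1, 1])))
})

test_that("the post hoc t map is a pooled two-sample t, blind minus sighted", {
  # worked example: blind {1,2,3} vs sighted {4,5,6}
  ms <- toy_map_set(matrix(c(1, 2, 3, 4, 5, 6), 6, 1),
    group = rep(c("blind", "sighted"), each = 3)
  )
  tm <- posthoc_ttest_map(ms)
  expect_equal(tm$t[1, 1, 1], -3.674, tolerance = 1e-3)
  expect_equal(tm$df, 4L)
  # oracle and antisymmetry on random data
  set.seed(3)
  v <- matrix(rnorm(12 * 4), 12, 4)
  grp <- rep(c("blind", "sighted"), each = 6)
  ms <- toy_map_set(v, group = grp)
  tm <- posthoc_ttest_map(ms)
  for (vox in 1:4) {
    tt <- t.test(v[grp == "blind", vox], v[grp == "sighted", vox],
      var.equal = TRUE
    )
    expect_equal(tm$t[vox], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tm$p[vox], tt$p.value, tolerance = 1e-10)
  }
  swapped <- toy_map_set(v, group = rev(grp))
  expect_equal(posthoc_ttest_map(swapped)$t, -tm$t, tolerance = 1e-12)
})

test_that("Brown-Forsythe handles equal spread at different locations", {
  ms <- toy_map_set(matrix(c(0, 2, 5, 7), 4, 1),
    group = c("blind", "blind", "sighted", "sighted")
  )
  bf <- brown_forsythe_map(ms)
  expect_equal(bf$BF_F[1, 1, 1], 0)
})

test_that("Brown-Forsythe equals the car::leveneTest median-centred oracle", {
  skip_if_not_installed("car")
  # the spec's worked groups
  x <- c(1, 2, 3, 4, 5)
  y <- c(10, 20, 30, 40, 50)
  ms <- toy_map_set(matrix(c(x, y), 10, 1),
    group = rep(c("blind", "sighted"), each = 5)
  )
  bf <- brown_forsythe_map(ms)
  oracle <- car::leveneTest(
    c(x, y), factor(rep(c("b", "s"), each = 5)),
    center = median
  )
  expect_equal(bf$BF_F[1, 1, 1], oracle[1, "F value"], tolerance = 1e-10)
  expect_equal(bf$BF_p[1, 1, 1], oracle[1, "Pr(>F)"], tolerance = 1e-10)
  # random data, many voxels
  set.seed(21)
  v <- matrix(rnorm(56 * 50), 56, 50)
  grp <- rep(c("blind", "sighted"), c(25, 31))
  ms <- toy_map_set(v, group = grp)
  bf <- brown_forsythe_map(ms)
  for (vox in seq(1, 50, by = 7)) {
    oracle <- car::leveneTest(v[, vox], factor(grp), center = median)
    expect_equal(bf$BF_F[vox], oracle[1, "F value"], tolerance = 1e-10)
  }
})

test_that("Brown-Forsythe is invariant to a joint location-scale transform", {
  set.seed(4)
  v <- matrix(rnorm(20 * 6), 20, 6)
  grp <- rep(c("blind", "sighted"), 10)
  f1 <- brown_forsythe_map(toy_map_set(v, group = grp))$BF_F
  f2 <- brown_forsythe_map(toy_map_set(3 * v - 7, group = grp))$BF_F
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("group variance maps, ratio masking and display threshold behave", {
  set.seed(6)
  v <- matrix(rnorm(56 * 30), 56, 30)
  grp <- rep(c("blind", "sighted"), c(25, 31))
  ms <- toy_map_set(v, group = grp)
  gv <- group_variance_and_ratio(ms, pool_cohorts = FALSE)
  expect_equal(
    as.vector(gv$S2_blind[, 1, 1]),
    apply(v[grp == "blind", ], 2, var),
    tolerance = 1e-12
  )
  # identical distributions: ratio near 1 and below the display threshold
  expect_lt(abs(median(gv$ratio[, 1, 1]) - 1), 0.5)
  expect_true(all(gv$ratio[, 1, 1] < gv$display_threshold))
  expect_equal(gv$display_threshold, 3)
  # ratio reported only inside a significance mask
  sig <- array(FALSE, dim = c(30, 1, 1))
  sig[1:5, 1, 1] <- TRUE
  gvm <- group_variance_and_ratio(ms, pool_cohorts = FALSE, bf_sig_mask = sig)
  expect_true(all(is.na(gvm$ratio[6:30, 1, 1])))
  expect_true(all(!is.na(gvm$ratio[1:5, 1, 1])))
})

test_that("cohort-pooled variance is invariant to cell demeaning", {
  set.seed(8)
  v <- matrix(rnorm(16 * 25), 16, 25)
  grp <- rep(c("blind", "sighted"), each = 8)
  coh <- rep(c("A", "B"), 8)
  ms <- toy_map_set(v, group = grp, cohort = coh)
  gv1 <- group_variance_and_ratio(ms)
  gv2 <- group_variance_and_ratio(demean_by_subgroup(ms))
  expect_equal(gv1$S2_blind, gv2$S2_blind, tolerance = 1e-12)
  expect_equal(gv1$S2_sighted, gv2$S2_sighted, tolerance = 1e-12)
})

test_that("ROI variability summary matches hand-computed variances", {
  v <- matrix(c(1, 2, 3, 4, 0, 0, 0, 0), 8, 1)
  ms <- toy_map_set(v, group = rep(c("blind", "sighted"), each = 4))
  roi <- array(TRUE, dim = c(1, 1, 1))
  out <- roi_variability_summary(ms, roi)
  expect_equal(out$S2_blind, 5 / 3, tolerance = 1e-3) # var(1,2,3,4)
  expect_equal(out$S2_sighted, 0)
  expect_true(is.nan(out$ratio))
  # all subjects identical
  ms2 <- toy_map_set(matrix(2, 6, 1), group = rep(c("blind", "sighted"), 3))
  out2 <- roi_variability_summary(ms2, roi)
  expect_equal(out2$S2_blind, 0)
  expect_error(
    roi_variability_summary(ms, array(FALSE, c(1, 1, 1))),
    "empty"
  )
})
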