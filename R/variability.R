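group_matrices <- function(maps, stat = NULL) {
  v <- map_values(maps, stat)
  g <- maps$participants$group
  list(blind = v[g == "blind", , drop = FALSE],
       sighted = v[g == "sighted", , drop = FALSE])
}

#' Voxelwise 2 x 2 ANOVA (group x cohort)
#'
#' Fixed-effects two-way ANOVA at every in-mask voxel via effect-coded
#' regression (blind/sighted = +1/-1, cohort A/B = +1/-1), which yields
#' Type-III-style 1-df F tests for both main effects and the interaction
#' in unbalanced designs.
#'
#' @param maps a `conn_map_set` with all four group x cohort cells
#'   nonempty.
#' @param stat `"t"` or `"beta"` (defaults to the set's choice).
#' @return list with 3D arrays `F_group`, `F_cohort`, `F_interaction`,
#'   matching `p_*` maps, and `df = c(1, n - 4)`.  Voxels with zero
#'   residual variance are NaN.
#' @export
anova_2x2_map <- function(maps, stat = NULL) {
  p <- maps$participants
  if (any(table(p$group, p$cohort) == 0)) {
    stop("every group x cohort cell must be nonempty", call. = FALSE)
  }
  Y <- map_values(maps, stat)
  n <- nrow(Y)
  g <- ifelse(p$group == "blind", 1, -1)
  co <- ifelse(p$cohort == "A", 1, -1)
  X <- cbind(intercept = 1, group = g, cohort = co, interaction = g * co)
  XtXi <- solve(crossprod(X))
  coef <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% coef
  df2 <- n - 4L
  sigma2 <- colSums(resid^2) / df2
  total_ms <- colMeans(Y^2)
  degenerate <- sigma2 <= total_ms * 1e-12
  out <- list(df = c(1L, df2))
  for (term in c("group", "cohort", "interaction")) {
    k <- match(term, colnames(X))
    Fv <- coef[k, ]^2 / (sigma2 * XtXi[k, k])
    Fv[degenerate] <- NaN
    out[[paste0("F_", term)]] <- vol_from_masked(Fv, maps$mask)
    out[[paste0("p_", term)]] <- vol_from_masked(
      stats::pf(Fv, 1, df2, lower.tail = FALSE), maps$mask
    )
  }
  out
}

#' Voxelwise post hoc group t contrast (blind - sighted)
#'
#' Two-sample pooled-variance t test at every in-mask voxel, signed
#' blind minus sighted, with two-sided p values and
#' `df = n_blind + n_sighted - 2`.
#'
#' @inheritParams anova_2x2_map
#' @return list with 3D arrays `t`, `p` and scalar `df`.  Voxels with zero
#'   pooled variance are NaN.
#' @export
posthoc_ttest_map <- function(maps, stat = NULL) {
  gm <- group_matrices(maps, stat)
  n1 <- nrow(gm$blind)
  n2 <- nrow(gm$sighted)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(gm$blind)
  m2 <- colMeans(gm$sighted)
  ss1 <- colSums(sweep(gm$blind, 2, m1)^2)
  ss2 <- colSums(sweep(gm$sighted, 2, m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  tval[se == 0] <- NaN
  list(
    t = vol_from_masked(tval, maps$mask),
    p = vol_from_masked(2 * stats::pt(abs(tval), df, lower.tail = FALSE),
      maps$mask
    ),
    df = df
  )
}

# Core Brown-Forsythe computation on two value matrices
# (subjects x voxels); exported map wrapper below.
bf_two_group <- function(x1, x2) {
  n1 <- nrow(x1)
  n2 <- nrow(x2)
  z1 <- abs(sweep(x1, 2, apply(x1, 2, stats::median)))
  z2 <- abs(sweep(x2, 2, apply(x2, 2, stats::median)))
  m1 <- colMeans(z1)
  m2 <- colMeans(z2)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- colSums(sweep(z1, 2, m1)^2) + colSums(sweep(z2, 2, m2)^2)
  df2 <- n1 + n2 - 2L
  Fv <- ifelse(ssb == 0, 0, ssb / (ssw / df2))
  list(F = Fv, p = stats::pf(Fv, 1, df2, lower.tail = FALSE), df = c(1L, df2))
}

#' Voxelwise Brown-Forsythe variance-homogeneity map
#'
#' At each in-mask voxel, tests whether the blind and sighted groups have
#' equal interindividual variance: the absolute deviations from each
#' group's *median* are submitted to a one-way ANOVA across groups
#' (median-centring makes the test robust to skew, unlike the classical
#' Levene test).  `F` has df `(1, n_blind + n_sighted - 2)`.
#'
#' @inheritParams anova_2x2_map
#' @return list with 3D arrays `BF_F` and `BF_p`, and `df`.
#' @export
brown_forsythe_map <- function(maps, stat = NULL) {
  gm <- group_matrices(maps, stat)
  stopifnot(nrow(gm$blind) >= 2, nrow(gm$sighted) >= 2)
  r <- bf_two_group(gm$blind, gm$sighted)
  list(
    BF_F = vol_from_masked(r$F, maps$mask),
    BF_p = vol_from_masked(r$p, maps$mask),
    df = r$df
  )
}

#' Per-group variance maps and the blind/sighted variance-ratio map
#'
#' Interindividual variance of the subject maps at each voxel, per group,
#' and their ratio (blind over sighted).  By default the variance is
#' pooled within group-by-cohort cells (deviations from each cell's own
#' mean, divided by `n_group - n_cells`): cohort mean offsets then cannot
#' masquerade as interindividual variability, and removing cell means
#' from the maps leaves the estimate exactly unchanged.  Set
#' `pool_cohorts = FALSE` for the plain per-group variance.  With
#' `normalize_within_group = TRUE`, each group's stacked maps are first
#' z-normalized by the group's overall mean and SD, removing group-level
#' scale differences (e.g. from cohort composition) before variances are
#' compared.  When a Brown-Forsythe significance mask is supplied, the
#' ratio is reported only inside it, matching the convention of showing
#' the direction of a variance difference only where one is established.
#'
#' @inheritParams anova_2x2_map
#' @param normalize_within_group z-normalize each group's data first.
#' @param pool_cohorts pool the variance within group-by-cohort cells.
#' @param bf_sig_mask optional logical 3D array (e.g. a corrected
#'   Brown-Forsythe map); the ratio is NA outside it.
#' @param display_threshold ratio display threshold carried in the result
#'   (conventionally 3 for figures).
#' @return list with 3D arrays `S2_blind`, `S2_sighted`, `ratio`, and the
#'   display threshold.  Voxels with zero sighted variance get NaN ratios.
#' @export
group_variance_and_ratio <- function(maps, stat = NULL,
                                     normalize_within_group = FALSE,
                                     pool_cohorts = TRUE,
                                     bf_sig_mask = NULL,
                                     display_threshold = 3) {
  v <- map_values(maps, stat)
  g <- maps$participants$group
  cohort <- maps$participants$cohort
  gm <- list(
    blind = v[g == "blind", , drop = FALSE],
    sighted = v[g == "sighted", , drop = FALSE]
  )
  cells <- list(
    blind = cohort[g == "blind"],
    sighted = cohort[g == "sighted"]
  )
  stopifnot(nrow(gm$blind) >= 2, nrow(gm$sighted) >= 2)
  if (normalize_within_group) {
    gm <- lapply(gm, function(m) (m - mean(m)) / stats::sd(as.vector(m)))
  }
  s2 <- lapply(names(gm), function(grp) {
    m <- gm[[grp]]
    if (pool_cohorts && length(unique(cells[[grp]])) > 1L) {
      ss <- 0
      for (ch in unique(cells[[grp]])) {
        mc <- m[cells[[grp]] == ch, , drop = FALSE]
        ss <- ss + colSums(sweep(mc, 2, colMeans(mc))^2)
      }
      ss / (nrow(m) - length(unique(cells[[grp]])))
    } else {
      colSums(sweep(m, 2, colMeans(m))^2) / (nrow(m) - 1L)
    }
  })
  names(s2) <- names(gm)
  ratio <- ifelse(s2$sighted > 0, s2$blind / s2$sighted, NaN)
  if (!is.null(bf_sig_mask)) {
    ratio[!bf_sig_mask[maps$mask]] <- NA_real_
  }
  list(
    S2_blind = vol_from_masked(s2$blind, maps$mask),
    S2_sighted = vol_from_masked(s2$sighted, maps$mask),
    ratio = vol_from_masked(ratio, maps$mask),
    display_threshold = display_threshold
  )
}

#' ROI-level variability summary
#'
#' Samples each subject's mean map value over an ROI, then computes the
#' unbiased variance of those values within each group and the
#' blind/sighted variance ratio -- the ROI analogue of the voxelwise
#' variance-ratio map.
#'
#' @inheritParams anova_2x2_map
#' @param roi_mask logical 3D array with at least one in-mask voxel.
#' @return list with `S2_blind`, `S2_sighted`, `ratio`, and the
#'   per-subject ROI means (`values`, named by subject).
#' @export
roi_variability_summary <- function(maps, roi_mask, stat = NULL) {
  in_roi <- roi_mask[maps$mask]
  if (!any(in_roi)) {
    stop("ROI is empty within the analysis mask", call. = FALSE)
  }
  vals <- rowMeans(map_values(maps, stat)[, in_roi, drop = FALSE])
  names(vals) <- maps$participants$subject_id
  g <- maps$participants$group
  s2b <- stats::var(vals[g == "blind"])
  s2s <- stats::var(vals[g == "sighted"])
  list(
    S2_blind = s2b, S2_sighted = s2s,
    ratio = if (s2s > 0) s2b / s2s else NaN,
    values = vals
  )
}
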