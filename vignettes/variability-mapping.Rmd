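---
title: "Mapping interindividual variability in seed-based functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping interindividual variability in seed-based functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconn)
```

## The question the package addresses

Most group fMRI analyses ask whether two groups *differ on average*.
`varconn` asks a complementary question: do two groups differ in how much
their members differ from one another?  The motivating application is
seed-based resting-state functional connectivity (RSFC) in congenitally
blind versus sighted adults: if shared visual experience standardizes the
functional wiring of visual cortex, its absence should show up as larger
*interindividual variance* of seed connectivity in the blind group, over
and above any change in mean connectivity — and regions that reorganize
(change their mean connectivity) should tend to be the same regions that
become more variable.

The package implements the full analysis chain needed to ask this
question quantitatively, and a synthetic-data generator that plants every
effect of interest with known ground truth, so each stage can be validated
end to end.

## The per-subject model

Each subject contributes one 4D BOLD run.  Preprocessing drops the first
two volumes (non-steady-state magnetization), then bandpass filters every
voxel series to 0.01–0.1 Hz with a zero-phase frequency-domain filter
(raised-cosine transition of width 0.005 Hz; the DC component is always
removed).  The seed predictor is the z-transformed spatial mean of the
seed mask.  Each z-scored voxel series is then fit by ordinary least
squares on

* the seed predictor,
* six motion parameters and their backward-difference derivatives (first
  row zero),
* mean white-matter and ventricle signals,
* optionally the global mean signal, and an intercept,

with all non-intercept regressors z-scored.  The seed predictor's *t*
statistic is the subject's connectivity map (the beta is retained
alongside; see "Numerical notes" for why group analyses read *t*).  Maps
are smoothed with a 6 mm FWHM Gaussian kernel for group analyses, with
in-mask renormalization so border voxels are unbiased.

### Site (cohort) normalization

The study design pools two cohorts acquired with different TR and scan
lengths, which scales the *t* maps differently (the *t* statistic grows
with the square root of the usable scan length).  `rsfc_maps()` offers
three normalization modes:

* `"cohort"` (the default used throughout the group pipeline): subtract
  each cohort's mean map level and divide by the cohort's average map SD.
  This removes the site scale and offset exactly in expectation while
  leaving within-cohort subject differences untouched.
* `"subject"`: z-normalize every individual map to mean 0, SD 1
  (`site_standardize()` applies the same transform to an existing map
  set).  This is the stricter reading of post hoc standardization, and it
  has a side effect worth understanding: the per-map mean and SD are
  *estimates*.  A subject with strong regional effects (or simply a noisy
  map-SD estimate — a smoothed map has few independent voxels) gets a
  slightly different scale than their neighbours, which feeds a small
  multiple of each subject's regional effects into every other voxel of
  their map.  In variance comparisons this inflates null-region variance
  ratios and compresses genuinely large deviations.  Because the site
  effect that the step exists to remove is a property of the *cohort*,
  not of the individual, the cohort-level mode is the package default;
  the per-subject mode remains available and fully tested.
* `"none"`: raw statistic maps.

Normalization constants are always computed from the unsmoothed maps:
the unsmoothed map has many more independent voxels, so its mean/SD are
estimated far more precisely; smoothing is applied afterwards.

## Group statistics

* **2×2 ANOVA** (`anova_2x2_map`): voxelwise fixed-effects
  group-by-cohort ANOVA via effect-coded regression, giving
  Type-III-style 1-df *F* tests that are well defined in unbalanced
  designs.
* **Post hoc contrast** (`posthoc_ttest_map`): pooled two-sample *t*,
  signed blind minus sighted.
* **Brown–Forsythe map** (`brown_forsythe_map`): at each voxel the
  absolute deviations from each group's *median* enter a one-way ANOVA
  across groups.  Median-centring makes the test robust to skewed
  distributions.  This is the variance-homogeneity map at the heart of
  the package.
* **Variance-ratio map** (`group_variance_and_ratio`): per-group
  interindividual variance and the blind/sighted ratio.  The group
  variance is pooled *within group-by-cohort cells* by default, so cohort
  mean offsets cannot masquerade as interindividual variability — and
  removing cell means from the maps (`demean_by_subgroup()`, the
  mean-controlled variant) leaves the estimate exactly unchanged.  A
  `normalize_within_group` flag reproduces the convention of reporting
  variances on each group's normalized scale.  Ratios are conventionally
  displayed only where the Brown–Forsythe map is significant, with a
  display threshold of 3.
* **ROI summary** (`roi_variability_summary`): per-subject mean map value
  over an ROI, then per-group variance and ratio.

## Cluster-extent correction

`estimate_smoothness()` implements the classic first-difference
variance-ratio estimator: along each axis, `var(diff)/2var` gives the
lag-one autocorrelation, converted to the FWHM of the Gaussian kernel
that would give white noise that autocorrelation; the three axis FWHMs
are combined geometrically.  `monte_carlo_min_cluster()` simulates null
volumes (white noise smoothed to the estimated FWHM, z-scored in-mask),
thresholds two-sided at the voxel *p*, and records the largest
face-connected cluster per sign; the minimum surviving extent is the
smallest size whose exceedance probability is at most alpha.
`threshold_and_label()` applies the resulting threshold to a real map,
forming clusters separately per sign (face adjacency).

The cluster-forming voxel *p* is a required, explicit parameter: results
depend on it strongly and there is no universally sensible default.

## Concordance and its spatial null

Lin's concordance correlation coefficient,

$$\mathrm{CCC} = \frac{2\,\mathrm{cov}(x,y)}
 {\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2},$$

with population (1/n) moments, measures *agreement* between two maps: it
is bounded by the Pearson correlation and additionally penalizes mean and
scale mismatch.  Testing a CCC between two brain maps against "no
association" must respect spatial autocorrelation, so
`spatial_permutation_test()` shuffles one map's in-mask values, convolves
the shuffled volume with a Gaussian kernel matched to the original map's
estimated smoothness, rescales the null map to the original in-mask mean
and SD (smoothing shrinks variance; without the rescale the null CCC is
biased toward zero), and recomputes the CCC.  p-values are two-sided with
the add-one correction.  `cross_seed_specificity()` computes the full
matrix of (variability map of seed i, group-difference map of seed j)
CCCs; the diagonal holds the coupled comparisons and the off-diagonal
entries are the cross-seed controls, compared after Fisher z transform.

## Connectivity fingerprints

`parcel_profiles()` reduces each subject's map to per-parcel means
(excluding the seed's own parcel), `hierarchical_cluster()` agglomerates
subjects by complete linkage on the correlation distance `1 - r`, and
`compare_group_distances()` asks whether one group's members are mutually
more dissimilar.  Its primary scheme averages each subject's distance to
their own group and compares those per-subject means with a pooled
two-sample *t* — pairwise distances are not independent observations, so
the naive pooled-pairs *t* is also returned but flagged.
`covariate_correlation()` correlates maps with a subject covariate
(Pearson) within a group and applies the cluster-extent correction.

## The synthetic generator

`simulate_study()` generates a two-cohort, two-group study from a
`synthetic_spec()`.  Each gray-matter voxel of subject *s* follows

$$y_v(t) = \bigl(w_{s,g(v)} + c_v\bigr)\, s(t) + r_{g(v)}(t)
 + \lambda_G G(t) + \text{couplings} + \varepsilon_v(t),$$

where

* `s(t)` is the subject's seed time course — a unit-variance Gaussian
  process band-limited to 0.01–0.1 Hz, so the analysis bandpass
  preserves it;
* `w` is the subject's true connectivity weight for the voxel's parcel,
  drawn from the group's planted mean and SD, plus an education increment
  in designated regions and clade offsets when subgroups are planted;
* `c_v` is a smooth, study-level *connectivity topography*: the stable
  within-parcel spatial structure real maps carry.  It is zero-mean
  within every parcel, so between-parcel profile structure is owned by
  the region means and parcel-mean time courses stay decoupled from the
  seed signal;
* `r_g(t)` is a per-parcel fluctuation (giving distinct seeds distinct
  time courses), `G(t)` a brain-wide physiological signal (what
  global-signal regression is meant to remove), plus motion-trace and
  tissue-signal couplings;
* `varepsilon` is temporally white noise, spatially smoothed to a known
  FWHM and rescaled to unit per-voxel variance.

White-matter and ventricle blocks carry their compartment signals; the
cohort's affine site effect (scale, then offset) is applied last; motion
tables are smooth random walks.

### Default study conditions

The defaults mirror the targeted study design: cohort A, 13 blind and 18
sighted subjects, TR 3 s, 180 volumes; cohort B, 12 blind and 13 sighted,
TR 2 s, 240 volumes (25 blind, 31 sighted in total); education years
uniform on 8–20.  The default grid is 10×10×8 voxels of 3 mm with 17
parcels — large enough that every parcel clears the 6 mm analysis kernel,
small enough that the repeated-study calibration experiments in the test
suite (hundreds of full simulations) remain quick.  Parcel seeds are
placed by farthest-point sampling and grown breadth-first with
balanced ring updates, giving compact, comparably sized parcels.

Planted effects (see `default_region_effects()`):

* parcels 3, 4 and 12 carry the *coupled* effect: higher blind mean
  (0.70 vs 0.05) and a 2.2-fold higher blind weight SD (0.66 vs 0.30,
  variance ratio 4.84);
* parcel 6 couples to education in the blind only (slope 0.05 per year,
  centred at 14 years), sized to give an ROI correlation near *r* = 0.7
  at n = 25;
* parcels 5, 10 and 15 are control-seed parcels with *no* coupling to
  the seed network, so cross-seed analyses seeded there are genuinely
  independent of the designated seed's effects — the role nonvisual
  control regions play in a specificity analysis;
* remaining parcels are null: their baseline means differ from parcel to
  parcel (the shared connectivity profile every subject carries, which is
  what makes fingerprint correlations meaningful) but are identical
  across groups, as are their SDs.

Effect magnitudes were chosen by a signal budget, not by trial against
any particular test outcome: after bandpass filtering the effective
degrees of freedom of a series are roughly `2 x bandwidth x duration`
(about 90 here), which puts an irreducible sampling variance of ~2–3
(squared *t* units) on every voxel's statistic; the planted weight SDs
are set so the planted interindividual variance dominates that floor at
the study's sample sizes, while remaining a small fraction of each map's
total spatial variance so normalization is stable.

### The recovery experiment

The variance-ratio recovery experiment (planted SD ratio 2.2, recovered
voxel ratio compared with 4.84) uses a deliberately minimal configuration:
no topography, no global signal, unsmoothed maps.  Each omitted ingredient
otherwise biases the *measurement* rather than the method: 6 mm smoothing
blends each parcel with its neighbours (attenuating the ratio toward 1 by
the squared kernel overlap), and per-subject multiplicative GLM noise
scales with the topography, adding equal variance to both groups.  With
those held out, the median recovered voxel ratio across repeated studies
sits within a few percent of the planted value, which is exactly what the
experiment is meant to demonstrate: the estimator itself is faithful, and
any shortfall in richer configurations is attributable to known,
documented geometry effects.

### Calibration experiments

Two facts shape how the suite checks calibration:

* *The Brown–Forsythe test's exact level.*  For Gaussian data at
  α = 0.05 the test rejects in 4.10% of samples at n = 25/31 and 4.5%
  at n = 40/40 (measured at 200,000 replicates; the implementation
  matches an independent reference to 1e-10).  The median-centring that
  buys robustness costs a little level at small n.  The type-I
  calibration experiment therefore uses a null study with 40 subjects
  per group, identical acquisition in both cohorts, and zero couplings
  outside the seed parcel — under those conditions map values are
  voxelwise independent, the groups' distributions are identical by
  construction, and a single study of ~6,000 voxels measures the level
  with a standard error of ~0.3 percentage points.
* *Shared per-subject noise.*  In richer configurations every subject
  carries map-wide shared components (their global signal and
  region-signal projections onto the seed estimate, their overall gain,
  their planted-effect draws), so voxelwise rejection rates within one
  study move together: the default study's null-region Brown–Forsythe
  rejection rate runs around 7–8% rather than 5%, not because the test
  is miscalibrated (the clean null study shows it is not) but because
  subjects' planted-effect draws shift their whole map.  Real data have
  the same property; averaging over studies, not voxels, is what
  isolates the test's level.

## Numerical notes

* *t versus beta.*  Group analyses read the *t* map by default.  Under a
  z-normalized GLM the beta saturates: beta `= w / sqrt(w^2 + sigma^2)`
  approaches ±1 as noise vanishes, so betas compress exactly the large
  couplings the variance analyses care about, while *t* stays
  proportional to the underlying weight.  Betas are stored alongside and
  selectable.
* Gaussian kernels use `sigma = FWHM / 2.355`, truncated at 4 sigma.
* Smoothness estimates below the voxel size return the voxel-size floor
  with a warning; constant maps are an error.
* Complete-linkage ties follow `hclust`'s deterministic behaviour for a
  given input order; the clustering result is invariant to subject order
  up to label renaming (verified by test).
* Degenerate voxel series (zero variance) yield NaN map values and are
  counted; zero-variance nuisance columns are left at zero and flagged.
* Permutation and Monte Carlo stages take explicit integer seeds and are
  bit-reproducible given them.
* The spatial permutation test conditions its null on the observed map's
  marginal moments and estimated smoothness; both are themselves noisy,
  so the test runs very slightly liberal on small grids (the calibration
  experiment measures rejection around 6–7% at a nominal 5% on a
  ~1,000-voxel mask, inside its acceptance band).  Larger masks and more
  iterations tighten this.

## Problem sizes used by the validation suite

The acceptance tests simulate full studies repeatedly: 50 studies for
variance-ratio recovery, 100 for the concordance and clade-recovery
experiments, 200 null analyses for the family-wise-error calibration,
500 replicates for the permutation-null calibration, and 40 runs for the
education-covariate experiment; desk-scale permutation tests use 1,000
iterations (production analyses should use 10,000–100,000).
`scripts/acceptance.R` recomputes the same quantities at moderately
reduced replication so a complete run stays in the range of minutes.

## What passing tests do and do not show

The generator emulates the *statistical* structure of a multi-site
resting-state study: band-limited shared fluctuations, planted group
means and variances, site scale/offset effects, motion/tissue/global
nuisance couplings, spatially smooth noise, subgroup structure and a
behavioural covariate.  It does not emulate hemodynamic response shapes,
physiological cycles (cardiac/respiratory aliasing), scanner drift or
artifacts, head-motion image displacement (motion enters only as
regressors and couplings), nonlinear registration error, or realistic
anatomy.  Passing the suite therefore demonstrates that the statistical
machinery is correct and calibrated under its assumptions — not that
those assumptions hold in any particular real dataset.  The same caution
applies to the single global latent signal: real connectomes have many
interacting networks, so cross-seed leakage patterns in real data are
richer than the generator's.
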