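---
title: "Functional connectivity density mapping: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Functional connectivity density (FCD) mapping summarizes resting-state BOLD
fMRI as a per-voxel count of functional connections. For a voxel $x_0$ and
the set of gray-matter voxels $\{x_j\}$, a connection exists when the
Pearson correlation of their (preprocessed) time series exceeds a
threshold, here the conventional $R > 0.6$ (strict inequality; ties at the
threshold are excluded). Three quantities are derived per voxel:

* **Global FCD (degree)** — the number of in-mask voxels with
  $r(x_0, x_j) > R$, self excluded.
* **Short-range (local) FCD** — the size of the cluster grown from $x_0$:
  starting from $S = \{x_0\}$, any in-mask voxel that correlates with $x_0$
  above the threshold *and* is spatially adjacent to a member of $S$ is
  added, iterating until no voxel can be added; the reported value is
  $|S| - 1$. The fixed point is a set, so the result does not depend on
  visitation order, and short $\le$ global holds by construction.
* **Long-range FCD** — global minus short-range: connections that are not
  reachable through a locally contiguous path of correlated voxels.

Each map is rescaled by its own in-mask mean
($\mathrm{FCD_{rescaled}} = \mathrm{FCD} / \overline{\mathrm{FCD}}$), so the
rescaled in-mask mean is exactly 1, and then smoothed with a 6 mm FWHM
Gaussian kernel. Rescaling precedes smoothing.

Group inference is a voxel-wise GLM of the (rescaled, smoothed) maps on a
group indicator plus age, gender (0/1) and total intracranial volume (TIV),
optionally mean frame-wise displacement (mFD). The group t map is
thresholded two-sided at single-voxel $p = 0.01$, suprathreshold voxels are
clustered under the 5 mm connection-radius neighborhood (18 offsets at 3 mm
isotropic voxels), and clusters smaller than a Monte-Carlo extent threshold
are discarded: the null distribution of the maximum cluster size is
simulated from Gaussian noise fields smoothed to 6 mm FWHM, standardized
within the mask, thresholded at the matching $|z|$ quantile, and the extent
cutoff is the smallest size whose empirical exceedance probability is at
most $\alpha = 0.05$. Surviving clusters seed a follow-up analysis: the
seed-mean time series is correlated with every gray-matter voxel, the r map
is Fisher-transformed ($z = \operatorname{arctanh} r$), smoothed (6 mm),
and compared between groups through the *same* inference code path.
Finally, patients' cluster-mean FCD is tested against clinical variables
(disease progression rate $(48 - \mathrm{ALSFRS\mbox{-}R})/\mathrm{duration}$,
duration, ALSFRS-R) by partial correlation controlling age, gender and TIV,
Bonferroni-corrected over all (cluster × variable) tests, with the number
of tests recorded in the output so the correction is auditable.

## Preprocessing

The pipeline starts from aligned, spatially normalized 4D data. Per
subject, in fixed order: (1) the first 10 volumes are discarded; (2) the
nuisance design — WM mean, CSF mean, six rigid-body motion parameters,
linear drift, intercept, and under the GSR arm the within-mask global mean
— is regressed out of every voxel by least squares (residuals are
orthogonal to every regressor); (3) an ideal frequency-domain boxcar keeps
0.01–0.08 Hz. The boxcar filter was chosen because its pass/stop behaviour
is exactly assertable (on-grid sinusoids pass with ratio 1, stopband power
is numerically zero) and it is idempotent; no filter design is claimed
beyond that. mFD follows the Power convention: the mean over transitions of
the summed absolute backward differences of the six parameters, rotations
mapped to arc length on a 50 mm sphere; it is computed on the retained
volumes by default (configurable). Subjects with mFD strictly above the
group mean + 2 SD (sample SD) are excluded — "strictly", mirroring the
rule's "higher than" wording.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `r_threshold` | 0.6 | correlation cutoff defining a connection (dimensionless) |
| `mask_prob` | 0.2 | GM probability above which a voxel enters the mask |
| `band` | 0.01–0.08 Hz | retained frequency band |
| `fwhm_mm` | 6 | map smoothing and assumed smoothness of the null fields |
| `voxel_p` | 0.01 | two-sided cluster-forming voxel threshold |
| `radius_mm` | 5 | cluster connection radius (18 neighbors at 3 mm voxels) |
| `n_iterations` | 5000 | Monte-Carlo iterations for the null distribution |
| `alpha` | 0.05 | corrected family-wise level |
| `n_discard` | 10 | dummy volumes dropped |
| `adjacency_connectivity` | 26 | growing-algorithm neighborhood |

Two deliberately exposed choices deserve note. The growing algorithm's
"adjacent" is not standardized; we default to the full 26-voxel
neighborhood (the nearest-neighbor usage of the local-FCD literature) and
expose 6/18 because short/long partitions depend on it. The centre voxel
is excluded from all counts so that short $\le$ global is guaranteed; an
include-self convention would shift both counts by one and cancel in the
long-range map.

## The synthetic cohort generator

Because no clinical scans ship with the package, every downstream stage is
validated on synthetic cohorts with *known* planted structure. A cohort
specification fixes, per subject, a 4D grid (default 3 mm isotropic voxels,
240 volumes at TR = 2 s, 10 of which the pipeline later discards), iid
Gaussian noise smoothed spatially to 6 mm FWHM and variance-renormalized
per voxel (the renormalization uses the exact per-voxel variance of the
reflected separable kernel, so unit variance is analytic, not estimated);
"blocks" of voxels sharing a latent signal $s_t$ with
$y = w s + \sqrt{1 - w^2}\,\varepsilon$ and $w = \sqrt{\mathrm{coupling}}$,
so the within-block pairwise correlation equals the stated coupling when
member noises are independent; and additive confounds — linear drift,
slow "physiological" series (the parents of the WM/CSF nuisance
regressors), and a motion-locked artifact derived from the subject's
random-walk motion trace. Group effects multiply a block's coupling for
one group, which is how connectivity deficits are planted. Covariates are
drawn once per cohort: age $\sim N(49, 10^2)$ truncated to [20, 80], TIV
$\sim N(1.6, 0.16^2)$ L, balanced gender, ALSFRS-R $\sim N(30.4, 6.8^2)$
rounded into [0, 48], duration $\sim N(22.9, 18^2)$ months floored at 1 —
plausible clinical ranges for a mid-sized ALS cohort.

What the generator does *not* emulate: hemodynamic response shape, scanner
artifacts (spikes, ghosting, drift nonlinearity), anatomical variability,
or the spatial covariance structure of real cortex. Passing tests
therefore demonstrate that the *algorithms* recover planted truth under
the stated noise model — not that any clinical effect would be detected at
these sample sizes.

One interaction matters when interpreting couplings: spatially smoothed
noise already correlates adjacent voxels (about $e^{-d^2/4\sigma^2}$),
which adds to a planted block's correlation. The planted-correlation
recovery test therefore runs with unsmoothed noise, where the
$w = \sqrt{c}$ mapping is exact; smoothed-noise cohorts simply sit on a
higher local-FCD baseline, as real data do.

## Numerical choices and degenerate inputs

* Correlations are computed from standardized series in centre-voxel
  chunks (`chunk_size`, default 512), so the full $N \times N$ matrix is
  never materialized; the chunked and full-matrix paths are tested to agree
  exactly. The growing BFS runs in compiled code over a precomputed
  in-mask neighbor graph.
* Zero-variance (constant) voxels inside the mask abort by default;
  `zero_variance = "zero"` assigns them degree 0 with a warning instead.
* Smoothing reflects at the mask bounding box and re-masks afterwards,
  avoiding edge attenuation; `fwhm = 0` is the exact identity. Kernels are
  discrete Gaussians truncated at $4\sigma$ and renormalized, so constant
  fields are preserved exactly.
* Fisher's transform clips $|r|$ at $1 - 10^{-7}$ so z maps stay finite
  for the GLM; seed voxels themselves stay in the map (r ≈ 1 near the
  seed) and clusters wholly inside a seed should be read accordingly.
* Cluster peaks are the maximum-|t| member, ties broken by lowest linear
  voxel index. Positive (control > patient) and negative contrasts are
  clustered separately and reported with their sign.
* The corrected extent threshold is the empirical tail quantile of the
  simulated max-cluster-size list — no distribution is fitted. Seeds for
  the simulation are required configuration; nothing falls back to the
  wall clock.
* The null fields use the stated 6 mm smoothness rather than estimating
  smoothness from residuals; only this stated-parameter mode is claimed.
* Each map is rescaled by its own in-mask mean; a shared-denominator mode
  (all three maps divided by the global map's mean) is available behind
  `shared_rescale` because the rescaling convention is not standardized.
  The rescaling mean is taken over the gray-matter analysis mask.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: the FCD
maps against a brute-force $O(N^2)$ correlation count plus a naive
set-expansion BFS (exact equality on dozens of random fixtures up to 500
in-mask voxels); cluster labeling against igraph's connected components;
the GLM against the closed-form pooled two-sample t; the partial
correlation against the inverse-correlation-matrix identity; the band-pass
against on-grid sinusoids. Calibration checks run the whole inference arm
on null cohorts: with 6 mm smoothness, ~5% of 200 null replicates yield a
surviving cluster at $\alpha = 0.05$ (binomial tolerance), and with
unsmoothed noise the suprathreshold fraction matches the voxel p. Power
checks plant a short-range coupling deficit (coupling 0.8, patient
multiplier 0.3, n = 20/group, 200 volumes, 24³ grid) and require a
surviving control > patient short-FCD cluster overlapping the planted
block in ≥ 90% of 20 cohort seeds, with an analogous seed-to-remote
decoupling check for the seed-FC arm (16³ grid, n = 16/group, 160
volumes, multiplier 0.2). The synthetic gray-matter template is an
ellipsoidal shell whose > 0.2 mask covers roughly a fifth to a third of
the field of view — a realistic gray-matter fraction that also sets the
per-subject problem size (a few thousand mask voxels). Null-distribution
tests use 500–1000 iterations rather than the production default of 5000;
the extent threshold stabilizes well before that at these mask sizes.

## Limitations

Only a single correlation threshold (0.6) is computed per run — no
multi-threshold sweep, no dynamic/windowed FCD. Inference offers only the
Monte-Carlo extent correction: no permutation inference, TFCE, or
random-field theory. Atlas labeling expects a caller-supplied label volume
and lookup table; no brain atlas is bundled, and the packaged
`synthetic_atlas()` is a toy parcellation for reporting plumbing only.
Spatial preprocessing (slice timing, realignment, normalization,
segmentation) is out of scope; inputs are assumed aligned, and WM/CSF mean
series are caller-supplied (or generator-supplied in synthetic runs).
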