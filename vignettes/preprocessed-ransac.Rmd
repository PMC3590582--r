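---
title: "Preprocessed RANSAC: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessed RANSAC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxransac)
```

## The problem

Appearance-based feature matching between two views of the same scene —
Harris corners matched by correlation, SIFT-style descriptor matches, or any
other front-end — yields a *putative* correspondence set `P` that mixes
correct matches (inliers of the underlying two-view geometry) with wrong
ones. Geometric verification estimates that geometry robustly and rejects
the outliers. For a general rigid scene the geometry is the fundamental
matrix `F` (the rank-2 3×3 matrix with `t(x2) F x1 = 0` for corresponding
homogeneous pixels); for a planar scene or rotating camera it is a
homography `H` (`x2 ~ H x1`).

RANSAC solves this by hypothesize-and-verify: draw a minimal sample (`s = 8`
correspondences for `F` with the linear solver, `s = 4` for `H`), fit a
candidate model, count how many correspondences agree with it within a
residual threshold, and keep the best-supported candidate. With confidence
`p` and inlier ratio `phi`, the number of draws needed so that at least one
sample is all-inlier is

```
N = log(1 - p) / log(1 - phi^s)
```

which explodes as `phi` drops (at `p = 0.95`, `s = 8`: `phi = 0.5` needs
766 draws, `phi = 0.3` needs ~46 000). This package implements a two-stage
framework that attacks exactly that regime: a cheap relaxation prefilter
extracts a reduced subset `E ⊂ P` with a much higher inlier ratio, RANSAC
runs on `E`, and the winning model's support is then counted on all of `P`,
so nothing is lost by the reduction.

## Stage 1: relaxation prefilter

The prefilter rests on a geometric regularity of correct matches: if two
correspondences are both correct, the distance between their points in
image 1 and the distance between their points in image 2 are nearly equal
(exactly equal under a rigid in-plane motion, approximately under moderate
viewpoint change). Wrong matches have no reason to preserve pairwise
distances.

For correspondences `c` and `d`, with `d1` and `d2` the image-1 and image-2
point distances and `r = |d1 - d2| / mean(d1, d2)` the relative length
distortion, the pairwise support is

```
support(c, d) = exp(-r / eps_r) / (1 + d1 / R)   if r < eps_r and d1 <= R
                0                                 otherwise
```

Nearby consistent pairs support each other strongly; the `1/(1 + d1/R)`
factor discounts distant neighbours, and pairs with distortion at or above
`eps_r` contribute nothing. The relaxation then iterates mutual
reinforcement: strengths start as each match's total support and are
repeatedly replaced by the support sum weighted by the neighbours' current
(max-normalized) strengths,

```
s0_i     = sum_j support(i, j)
s(k+1)_i = sum_j support(i, j) * shat(k)_j
```

so a match backed by *other well-supported matches* gains weight while
isolated or inconsistent matches decay toward zero. The iteration stops
after `q_max` sweeps (default 60) or when the normalized strengths change by
less than `convergence_tol`. The reduced set `E` keeps the matches with
strength strictly above the mean strength of `P` (a scale-free rule;
top-k and absolute-threshold rules are available in
`relaxation_config()`).

The functional form above is this package's concrete instantiation of
distance-consistency relaxation labeling; the constants are exposed in
`relaxation_config()`:

| parameter | default | meaning |
|---|---|---|
| `q_max` | 60 | relaxation sweep cap |
| `neighborhood_radius` | image-1 diagonal / 8 (100 px if size unknown) | support radius, px |
| `eps_r` | 0.3 | relative length-distortion cutoff (dimensionless) |
| `convergence_tol` | 1e-4 | early-stopping change threshold |

Two safety properties are deliberate: strengths are invariant under rigid
motions of either image (only pairwise distances enter), and when the
selection rule would leave fewer matches than a minimal sample — e.g. when
all strengths tie — the pipeline falls back to `E = P` with a signalled
condition, so preprocessing can never make verification fail where plain
RANSAC would succeed.

What the prefilter assumes, and when it degrades: inter-point image
distances must be *roughly* preserved between the views. Strong perspective
distortion, large depth discontinuities inside the neighborhood radius, or
heavy zoom violate this and will cost true matches their support. The
selection then errs toward a smaller, purer `E`, which costs nothing in
correctness (support is always re-counted on `P`) but can reduce the
speedup.

## Stage 2: adaptive RANSAC with bucketed sampling

**Minimal solvers.** `F` comes from the normalized 8-point algorithm:
Hartley normalization of both point sets (centroid at the origin, mean
radius `sqrt(2)`), null vector of the 8×9 epipolar design matrix by SVD,
rank-2 enforcement by zeroing the smallest singular value after
denormalization. `H` comes from the normalized DLT on 4+ points. Both
reject degenerate samples (design-matrix rank below 8, i.e. an ambiguous
null space) and canonicalize the output to unit Frobenius norm with the
largest-magnitude entry positive, so model comparisons are well defined.

**Residuals.** The verification residual for `F` is the Sampson distance,
the first-order approximation of a correspondence's geometric distance to
the epipolar constraint manifold; for `H` the symmetric transfer error.
The default inlier threshold is 1.5 px — three standard deviations of the
default synthetic noise level, and a common working value for pixel-accurate
front-ends. It is a free parameter (`ransac_config(inlier_threshold = )`,
CLI `--threshold`).

**Bucketed sampling.** Minimal samples whose points are spatially clustered
condition the solvers badly. The bucket grid partitions the bounding box of
the image-1 points into `b × b` cells (`b = 8` by default, the smallest
value guaranteeing 8 cells along one axis even for degenerate layouts),
drops empty cells, and draws each minimal sample from `s` mutually distinct
cells, one match per cell, all uniformly. When fewer than `s` cells are
occupied the draw falls back to uniform sampling over all matches rather
than failing. Buckets are *not* weighted by occupancy.

**Adaptive termination.** `phi` is unknown beforehand, so the loop keeps
the bound current: after every improvement of the best consensus it
recomputes `N` from the best inlier ratio seen so far and stops once the
iteration count reaches `min(N, n_max)` (`n_max = 10000` guards
`phi -> 0`). Degenerate samples consume an iteration, ties keep the
earlier model, and the whole loop is a deterministic function of the seed.

**Final refit.** The winning model is refit by the same linear solver on
all of its inliers, the mask reclassified, and the refit repeated while the
support does not drop (at most 10 rounds). The guard matters: a plain
least-squares refit on a consensus that still contains a few outliers can
drift badly — in the worst observed case losing the entire consensus — so a
refit that loses support is discarded and the previous model kept. This is
still a final consensus polish, not in-loop local optimization (LO-RANSAC
variants are out of scope).

**Two-stage orchestration.** `preprocessed_ransac()` runs relax → select →
RANSAC on `E` (bucketed by default) → `classify_inliers()` on the full `P`,
and reports `support_P / |P|` as the `"k/n"` string. In all paired
comparisons the *plain* arm samples uniformly: bucketing is part of the
improved framework, not of traditional Monte-Carlo RANSAC. (Empirically,
bucketing the raw putative set also restricts the hypothesis pool slightly
at this problem scale, which is another reason not to hand it to the
baseline.)

## The synthetic scene generator

All quantitative claims are exercised on generated scenes with exact ground
truth. `generate_f_scene()` builds a random camera pair — shared pinhole
intrinsics with focal length 0.9–1.1 image widths, principal point at the
image centre; relative rotation of 5–15° about a random axis; baseline
0.25–0.5 scene units — and back-projects uniformly sampled image-1 pixels to
depths 4–8, keeping points visible in both views. The true `F` follows from
the pose. `generate_h_scene()` intersects the viewing rays with a plane
(tilt ≤ 20°) instead, and the induced homography
`H = K (R + t n'/d) K^-1` is the truth.

Inliers get isotropic Gaussian noise of `sigma/sqrt(2)` px in *each* image,
so the Sampson residual scale matches `sigma`; the default `sigma = 0.5` px
reflects a good corner localizer. Outliers pair independently uniform
points and are **rejected-and-resampled** until farther than the inlier
threshold from the true model — without this the requested inlier ratio
would be biased upward and precision/recall targets ill-defined. Exactly
`round(phi * n)` inliers are produced and the rows shuffled.

What the generator does *not* emulate: repeated textures (which produce
spatially-correlated outliers rather than uniform ones), localization error
that varies with feature scale, occlusion structure, and photometric
effects. Passing tests on these scenes therefore validate the geometric
machinery and the enrichment mechanism, not the behaviour of any particular
detector on real images — which is why the front-end accepts external
correspondence files.

The benchmark problem sizes used by the test-suite and the acceptance
script — scenes of 200–300 matches, 50–100 seeds per condition — are chosen
as the smallest sets on which median statistics across seeds are stable.

## Behaviour across the inlier-ratio range

The package's central empirical property, exercised by
`benchmark_ransac()`: relaxation enriches the reduced set's inlier ratio
well above `phi` for `phi` in 0.2–0.5, and the preprocessed pipeline's
median iteration count is far below plain RANSAC's whenever `phi <= 0.6`
(at `phi = 0.3` the adaptive bound on `P` exceeds the 10000-iteration cap
while the bound on `E` is a few dozen).

One honest caveat. At high inlier ratios (`phi >= 0.6`) the two approaches
cost about the same *in total runtime*, because plain RANSAC's iteration
count is already small and the preprocessing adds an `O(n^2 q)` relaxation
overhead. Their *iteration counts*, however, do not equalize: enrichment
saturates near `phi_red ~ 1`, so the loop on `E` still terminates in a
handful of draws while the loop on `P` needs a few dozen. Under adaptive
termination the iteration count is a function of the scored set's inlier
ratio alone, and preprocessing improves that ratio at every `phi`; only the
*relative advantage* vanishes at high `phi` once the relaxation overhead is
counted.

## Numerical choices and degenerate inputs

- Coordinates are 0-based pixel centres, x right, y down; homogeneous third
  coordinate fixed to 1, everywhere.
- Hartley normalization is unconditional inside both solvers; the
  unnormalized 8-point algorithm is numerically unusable.
- Degeneracy tests are relative: design-matrix rank deficiency at
  `1e-8 * sigma_max`, rank-2 check at `1e-10 * sigma_max`, homography
  nonsingularity at `|det| > 1e-12` after normalization.
- A correspondence whose Sampson denominator vanishes (all four gradient
  terms zero) or that a homography maps to the line at infinity has no
  defined residual: direct residual calls raise a classed error naming the
  correspondence; `classify_inliers()` classifies it outlier and signals a
  message.
- Coincident points in a pair give relaxation support 0; a zero-extent
  bucket-grid axis degenerates to a single stripe; an all-tied strength
  vector selects `E = P`.
- All randomness flows from a single integer seed (`set.seed()` at pipeline
  entry; the compiled loop draws from R's RNG stream), so results are
  reproducible byte-for-byte, and the seed is echoed in the JSON report.

## Known limitations

- The 7-point solver, calibrated/essential-matrix estimation and radial
  distortion are out of scope; so are PROSAC-style quality-ordered sampling
  and LO-RANSAC.
- The relaxation prefilter assumes approximate pairwise-distance
  preservation; extreme perspective or large zoom breaks the assumption.
- The front-end is deliberately minimal (Harris + mutual-best NCC); for
  production matching feed external correspondences via the TSV interface.
- Minimal-solver accuracy at `sigma > 0` limits plain RANSAC's recall; the
  guarded iterated refit recovers most, not all, of it. The preprocessed
  pipeline is less affected because its hypotheses come from a nearly clean
  set.
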