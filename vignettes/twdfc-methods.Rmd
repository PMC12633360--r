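---
title: "Track-weighted dynamic functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-weighted dynamic functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Track-weighted dynamic functional connectivity (TW-dFC) fuses a structural
tractogram with resting-state BOLD fMRI into a single 4D image. Every
streamline retained in the analysis has one endpoint inside a seed region
(here, a bilateral structure such as the hippocampus) and the other in a
distal grey-matter region. The streamline is assigned a *dynamic functional
weighting*: the sliding-window Pearson correlation between the BOLD series
sampled at its two endpoint voxels,

$$\mathrm{FC}_s(w) \;=\;
  \mathrm{corr}_{\omega}\!\big(x_{\mathrm{seed}(s)}[t_w .. t_w+W-1],\;
                               x_{\mathrm{distal}(s)}[t_w .. t_w+W-1]\big),$$

where the correlation is taper-weighted: means, variances and covariance
inside each window use Hamming weights
$\omega_n = 0.54 - 0.46\cos(2\pi n/(W-1))$. The weighting of every
streamline is then projected onto all voxels the streamline traverses, and
where several streamlines cross one voxel their weightings are averaged:

$$\mathrm{TWdFC}(v, w) \;=\;
  \frac{\sum_{s \ni v} \omega_s\, \mathrm{FC}_s(w)}{\sum_{s \ni v} \omega_s},$$

with $\omega_s = 1$ by default, or a per-streamline weight (e.g. SIFT2)
when weighted averaging is requested. The result has one frame per window:
grey-matter dynamic coupling painted onto the white-matter pathways that
connect the correlated regions. Downstream, the 4D maps of several subjects
are temporally concatenated, decomposed into spatial components, and the
seed region is parcellated by k-means on the per-voxel component profiles;
the resulting bilateral clusters then serve as seeds for conventional
resting-state FC group contrasts.

## Parameters that matter

* **Window width `width` (default 85 volumes).** At TR = 0.72 s this is a
  61.2 s window, long enough for a stable correlation estimate yet short
  enough to resolve slow coupling changes. `window_duration()` reports the
  span in seconds.
* **Stride (default 1 volume).** The window step is not fixed by the
  method's description; stride 1 is the densest choice and yields
  $N = T - W + 1$ frames. Larger strides subsample the window sequence.
* **Taper (default `hamming`).** The taper enters the correlation itself
  (weighted moments), not merely frame selection. A `rectangular` mode
  reduces each window to the plain Pearson correlation and is used by the
  oracle tests.
* **Rasterization step `step_mm` (default half the smallest voxel size).**
  Streamlines are resampled by arc length before voxel assignment; halving
  the step must not change the voxel set of straight segments (tested), and
  each streamline contributes at most once per voxel regardless of how many
  samples land in it.
* **Streamline weights (default off).** The voxel average is unweighted
  unless `use_weights = TRUE`; per-streamline weights are read from file
  and validated against the streamline count, never computed here.
* **Preprocessing.** Volumetric Gaussian smoothing takes an FWHM in mm
  (6 mm in the reference configuration), implemented as separable
  convolutions with edge-reflecting padding (mass-preserving; with a mask
  the convolution is mask-renormalised so signal does not bleed across the
  boundary). The temporal bandpass (0.01–0.1 Hz reference band) defaults to
  an FFT hard-window filter because it makes the retention contract exact
  and testable; the filter family behind the reference analysis is not
  specified, so an order-2 forward-backward Butterworth is provided as an
  alternative mode. Both are zero-phase.
* **Component count.** `decompose()` selects the smallest number of
  principal components whose cumulative eigenvalue fraction reaches
  `var_threshold` (default 0.98) before the fixed-point ICA rotation; a
  fixed count can be given instead.
* **Cluster count `k`.** A required input; 4, 6 and 8 are the documented
  reference solutions, with k = 6 the one examined in detail.

## Interpretations and design choices

Several steps of the source pipeline are under-specified and are
implemented here as explicit, documented choices:

* **"Thresholding the z-score maps at p > 0.5"** is read as mixture-model
  posterior thresholding — the standard meaning in the MELODIC toolchain: a
  Gaussian mixture is fitted to each component's z values and voxels whose
  posterior probability of belonging to the signal class exceeds 0.5 are
  kept. Two refinements make this robust: the number of classes (1 or 2) is
  chosen by BIC, so a pure-noise component has no signal class and is
  zeroed entirely (a plain two-class fit would arbitrarily split noise and
  keep about half of it); and the signal class is the higher-variance
  class, with ties within 10% broken by the larger absolute mean. A plain
  `|z| > 1.645` mode is provided as a fallback and as the alternative
  reading of the phrase.
* **Thresholded versus raw features.** Cluster features default to the
  thresholded (sparsified) z-scores; passing an unthresholded component set
  to `build_features()` preserves raw z profiles.
* **Both-endpoints-in-seed streamlines** are excluded by default: each
  retained streamline should link the seed to a distal region. A
  `policy = "both"` flag keeps them for sensitivity analyses.
* **Bilateral merging** pairs left and right clusters by mirroring right
  centroids across the midplane and solving the optimal one-to-one
  assignment; merged clusters are lettered A, B, C from anterior to
  posterior. An explicit override mapping reproduces any published pairing
  verbatim.
* **Group contrasts** are paired, one-tailed t-tests on Fisher-z FC maps
  (the same subjects provide both maps of every contrast); an unpaired
  pooled-variance option is available since the source wording ("one-way
  t-tests") does not fix the design. Each of the six directional contrasts
  is its own Benjamini–Hochberg FDR family; corrected q-values are
  converted to z by $\Phi^{-1}(1-q)$, capped at $|z| = 8.2$ to keep maps
  finite, and thresholded at 1.645 (one-tailed p = 0.05).
* **MELODIC is replaced** by PCA whitening plus symmetric fixed-point ICA
  (logcosh contrast) with explicit seeding; z-scoring of spatial maps is
  per-component standardisation. When residual components are Gaussian
  noise the ICA rotation has no stable fixed point; after its retries the
  decomposition returns the final rotation with a warning rather than
  failing, since any rotation of a Gaussian subspace is an equally valid
  basis and the variance criterion deliberately retains such components.

## Numerical conventions

* Voxel indices are 0-based; world-to-voxel assignment rounds
  half-away-from-zero, so a point exactly on a voxel-face boundary belongs
  to the higher index.
* TCK vertices are stored as float32; a round-trip through `write_tck()` /
  `read_tck()` is bit-exact at that precision and preserves streamline
  order.
* Windows with weighted variance below $10^{-12}$ in either series yield a
  weighting of 0 and are counted in the map's provenance rather than
  propagating NaN.
* All finite TW-dFC values are clipped to $[-1, 1]$; voxels traversed by no
  streamline are NaN and are excluded from the analysis mask during
  concatenation (per-subject, per-voxel mean-centred; remaining NaN frames
  imputed as 0).
* The map is bit-identical under any permutation of the input streamlines:
  window correlations avoid BLAS matrix-vector kernels (whose accumulation
  order is layout-dependent at the last bit) and projection accumulates
  contributions in a canonical order.
* k-means uses k-means++ initialisation with 10 restarts, keeps the lowest
  inertia, relabels clusters by descending size and breaks ties by the
  lexicographically smaller centroid, so results are reproducible given
  the seed.

## The synthetic phantom

Real acquisitions of the reference analysis (Human Connectome Project
scans) are not redistributable at package scale, so validation runs on a
synthetic phantom that reproduces the *statistical structure* the method
assumes:

* a 32 × 32 × 24 grid of 2 mm voxels with the midline at world x = 0;
* two mirror-image ellipsoidal seed bodies (semi-axes 5 × 16 × 5 mm,
  centres at x = ±14 mm) split into three contiguous slabs along the long
  axis — the planted subregions;
* six 8 mm cuboid target regions on the lateral walls, placed so that each
  bundle exits the seed quickly instead of running along it (which would
  contaminate neighbouring subregions' voxels);
* 200 streamlines per (side, subregion), drawn as quadratic curves from a
  jittered seed-voxel centre to a jittered target-voxel centre with a
  perturbed midpoint, resampled at 1 mm — every streamline has exactly one
  endpoint in the seed. Targets follow a row-stochastic connectivity matrix
  (default: 0.8 to the designated target); the right hemisphere uses the
  matrix with target columns rotated by half, so the two sides project to
  disjoint preferred targets;
* BOLD series of T = 300 volumes at TR = 0.72 s. A latent Markov chain
  with geometric dwell (mean 75 volumes, about four state epochs per run)
  switches between two coupling states; region signals are drawn from the
  active state's multivariate normal and AR(1)-smoothed (φ = 0.3,
  variance-preserving) to approximate BOLD autocorrelation without a full
  haemodynamic model. Every voxel adds iid N(0, 0.5²) noise to its
  region's unit-variance signal; background voxels carry unit-variance
  noise.

The default per-state couplings give the six bundles distinct state-swing
amplitudes (+1.2, +0.8, +0.4 on the left; the negatives on the right), so
each (side, subregion) has a distinguishable dynamic signature. T = 300
rather than a full-length run keeps the default test suite and acceptance
runs at desk scale (a 5-subject pipeline — tractograms, BOLD, TW-dFC maps,
ICA, clustering — completes in well under a minute per subject); the
config scales up.

What the phantom does *not* emulate: haemodynamic response functions, head
motion, physiological noise, spatial autocorrelation of the noise, partial
voluming, or realistic fibre geometry. Passing the recovery tests
therefore shows that the implementation is faithful to the model and that
the pipeline can recover planted structure under the model's own
assumptions — not that it would recover anatomy from real data.

## Validation surface

The test suite checks, among others:

* oracle equivalence of the full TW-dFC map against an independent
  triple-loop implementation (tolerance 1e-12);
* the static limit: with a single coupling state, the per-voxel window-mean
  TW-dFC stays within 0.1 of the full-length endpoint correlation;
* end-to-end recovery: the k = 6 parcellation of the default 5-subject
  phantom, merged bilaterally, reaches an adjusted Rand index above 0.8
  against the planted subregions;
* type-I control and power of the group contrasts on null and
  planted-effect cohorts of 20 synthetic subjects (the planted effect
  raises one bilateral cluster's coupling to one target by 0.25 over a
  0.10 baseline, chosen for positive semidefiniteness of the coupling
  matrix; the realised per-voxel effect size is measured, not tuned).

## Known limitations

* Volumetric only; surface/grayordinate processing is out of scope.
* TCK is the only tractogram dialect; tractography itself, FOD estimation
  and SIFT2 weight computation are upstream of this package.
* No automatic selection of the cluster count k.
* The mixture threshold fits each component independently; no spatial
  regularisation.
* Endpoint sampling is nearest-voxel by design, matching the voxel
  resolution of the endpoint table; no trilinear interpolation.
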