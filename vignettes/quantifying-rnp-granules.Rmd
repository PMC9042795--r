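---
title: "Quantifying RNP granules: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNP granules: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpgranules)
```

## Scope

RNP granules — mesoscale condensates of mRNAs and RNA-binding proteins,
exemplified by the *oskar* transport granules of the *Drosophila* oocyte —
are characterized in imaging studies through a recurring set of derived
quantities: size and shape distributions from super-resolution stacks,
molecular mobility from FRAP, absolute copy numbers and molar
concentrations from single-molecule FISH intensities and calibration
ladders, object-based colocalization corrected for chance, partition
coefficients between condensed and dilute phases, and the anteroposterior
(AP) displacement of the signal's center of mass. `rnpgranules` implements
these estimators together with a seeded synthetic-microscopy generator, so
that every estimator can be exercised against exact ground truth without
any raw imaging data.

This vignette documents the models, the parameter conventions (units,
defaults, why), what the synthetic data emulate and what they deliberately
do not, and the numerical decisions a maintainer would want to know.

## Conventions

All lengths at every interface are nanometres. Arrays are indexed
`[z, y, x]` (or `[y, x]` in 2D); `voxel_size` is nm per axis in the same
order. Physical coordinates are measured from the `(0, 0, 0)` corner of the
grid, so the centre of voxel `i` sits at `(i - 0.5) * voxel_size`. Volumes
are reported in µm³ (litres where molar concentrations are formed),
concentrations in molar. Every generator takes an integer seed; each
generator draws from its own child stream derived from that seed, so stages
re-run independently still reproduce bit-identically.

## The synthetic-microscopy generator

`generate_granule_image()` renders granules as ellipsoids of a sampled
diameter filled at uniform density, then applies optics and noise in
physical order: Gaussian PSF blur, Poisson photon resampling, additive
Gaussian read noise. The rendered total above background is exactly
`copies * unit_intensity` per granule, which makes photon conservation a
testable invariant rather than an approximation.

Defaults encode the conditions the estimators are meant for: a Gaussian
diameter distribution of 400 ± 129 nm (the in vivo STED-measured granule
cohort), spherical granules (`axis_ratio = 1`), and a 60 × 40 × 40 nm voxel
grid (the 3D STED acquisition geometry). Diameters are rejection-truncated
to exceed two voxels' physical extent, because sub-voxel spots are not
measurable and real granules are well above that floor. Placement is
uniform with a pairwise `min_separation` (rejection sampling with a bounded
retry budget; an over-packed request fails with an explicit "field too
crowded" error rather than degrading silently).

Two voxelization modes exist. The default tests voxel centres against the
ellipsoid (hard in/out), which keeps the segmentation-support semantics of
a two-level image exact. For sub-voxel *shape* measurements this
quantization is the dominant error source: the transverse offset of a
granule's centre can erode a line profile by up to a voxel and move a 2:1
axis ratio by ~10%. `antialias = TRUE` instead integrates the ellipsoid's
coverage over each boundary voxel (4³ subsamples), which removes that
jitter while preserving exact photon conservation. Shape validation uses
the antialiased mode; segmentation validation uses the hard mode.

The other generators follow the same pattern: `generate_two_channel_field()`
places exactly `round(fraction × n_ref)` jittered partners and fills the
remainder uniformly (ground truth records the pairing);
`generate_frap_trace()` evaluates the closed-form recovery model under
reference-channel decay and additive noise; `generate_intensity_population()`
produces `k × unit × (1 + ε)` spot intensities (or Poisson photon counts)
with copy weights emulating nurse-cell particles dominated by one- and
two-copy mRNAs; `generate_polarity_field()` places point granules in the
posterior half of a mask with a chosen probability;
`generate_calibration_ladder()` images a linear detector response.

What the generator does **not** emulate: vectorial or STED-depletion PSFs,
ooplasmic flows and motor transport, granule fusion or aging, detector
saturation, chromatic shifts. Tests passing on these synthetics therefore
validate the estimators' correctness and calibration on their stated
models — not robustness to every optical artifact of a real microscope.
The noise model (Poisson + Gaussian read noise) and SNR are configurable
because real acquisitions vary; the defaults are a conventional
photon-counting model, not a measured instrument profile.

## Segmentation

`intermodes_threshold()` implements the classical Intermodes rule: the
256-bin histogram is smoothed with a 3-point moving mean (zeros outside
the range) until exactly two strict local maxima remain; the threshold is
the midpoint of the two mode bins. Histograms that pass from ≥3 modes
directly to ≤1, or that never become bimodal within 10,000 iterations, are
rejected with a "not bimodal" error — flat and single-peak inputs have no
Intermodes threshold. Binning for `threshold_image()` spans `[min, max]` of
the channel in 256 equal-width bins; the returned threshold is the centre
of the (possibly half-integer) midpoint bin mapped back to intensity units.

Threshold comparisons are strict (`intensity > t` is foreground), so ties
fall to background and a constant image yields an empty mask under a
threshold at its value. Labeling defaults to full connectivity
(26-neighborhood in 3D, 8 in 2D) because small blurred spots fragment under
face-only connectivity; both are available. Touching granules are not
watershed-split: separation is controlled upstream (physically, or by
`min_separation` in the synthetics), and the package makes no claim of
equivalence with commercial segmenters beyond the stated threshold rules.

`measure_objects()` is pure voxel arithmetic: volume = voxel count × voxel
volume; equivalent diameter = the sphere (circle) of equal volume;
integrated intensity = mean × count exactly, so object intensities plus
background partition the image total with no leakage.

## Morphometrics

The aspect ratio follows the line-profile definition: principal directions
come from the intensity-weighted second-moment tensor of the object;
each axis length is the full width at half maximum (FWHM) of the
background-subtracted profile through the intensity-weighted centroid
along that direction, with linear interpolation between voxels
(sampling step = ¼ of the smallest voxel edge). The endpoint criterion for
"axis length" is genuinely open in the field; FWHM was chosen because it is
robust to background pedestals and matches optics convention. Background is
the median intensity of the one-voxel shell around the object's bounding
box. A profile that never falls below half maximum raises an "unbounded
profile" error; objects spanning fewer than 3 voxels on a probed axis are
rejected as unmeasurable.

The size-distribution fit is the Gaussian MLE (sample mean, n−1 SD) — the
model under which a granule cohort's "diameter = mean ± SD" statement is
defined. The volume–intensity relation operationalizes "concentration does
not increase with granule volume" as an estimable quantity: per-granule
concentration proxy = integrated intensity / volume, regressed on volume by
OLS, reported as slope ± SE so "no increase" is a testable
slope-consistent-with-zero statement instead of a binary claim.

The partition coefficient is mean intensity inside the condensate mask
over mean intensity of the dilute phase. Whether a buffer zone around
condensates belongs to the dilute phase is not standardized; the dilute
phase here is the complement of the mask dilated by `exclusion_halo`
voxels (default 1, reported in the result) so blur bleed-over does not
contaminate the denominator. Polygon-ROI integrated density uses the
even-odd rule on voxel centres, per slice in 3D.

## FRAP kinetics

The recovery model is the single-exponential
`FRAP(t) = I0 + I1·(1 − e^{−(t − t_bleach)/τ})`, with `I0` the normalized
intensity just after bleach and `I1` the dynamic range of recovery. Derived
quantities are the immobile fraction `(1 − I0 − I1)/(1 − I0)` and the
half-time `t½ = τ·ln 2`. `t_bleach` is the timestamp of the first
post-bleach frame — the bleach event itself is never sampled.

`normalize_trace()` performs double normalization: background subtraction,
frame-wise division by the reference ROI (cancelling acquisition
photobleaching), division by the pre-bleach mean of that ratio (pre-bleach
plateau ≡ 1, using all pre-bleach frames — acquisitions here record three),
then an affine rescale pinning the first post-bleach frame to 0 ("scaling
the dynamic range from 0 to 1"). Both anchors are recorded as attributes.
The rescale is an affine reparametrization: τ and the immobile fraction are
invariant under it, while `I0 → (I0 − b)/(1 − b)` and `I1 → I1/(1 − b)`
with `b` the first post-bleach value. When fitted parameters are to be
compared with ground truth defined on the plateau-normalized scale, use
`rescale = FALSE`; the parameter-recovery tests do exactly that. A missing
reference degrades to single normalization with a warning; a bleach frame
not below the pre-bleach mean warns "no bleach detected".

`fit_recovery()` is nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`) over the post-bleach frames with a deterministic, seed-free
initialization: `I0` from the first post-bleach value, `I1` from the final
recovery level, τ from a linear scan for the time of
`I0 + (1 − 1/e)·I1`. Failures restart from deterministically jittered
values a bounded number of times and otherwise error with the best residual.
On noiseless model traces the fit recovers parameters to ≤10⁻⁶ relative
error with residual RMS below 10⁻⁸ (it is an exact model-class fit). Under
noise, τ precision is set by how much of the recovery the sampling covers:
the test grid samples ~6τ at τ/100 intervals, the study-protocol check uses
0.35 s frames over ~55 s.

## Abundance calibration

Copy numbers come from a 1D Gaussian mixture fitted to spot intensities by
EM, with the log-likelihood asserted non-decreasing at every iteration and
convergence at a relative change of 10⁻⁸ (cap 1000 iterations).
Initialization is deterministic — quantile-spaced means, pooled SD, uniform
weights — and degenerate runs (collapsing SD or vanishing weight) restart
with seed-derived ±10% jittered means, at most 10 times. When a range of K
is given (default 1–4, since "several Gaussian components" is the model but
K is not known a priori), K is selected by BIC. A minimum of 10
observations per component is enforced.

The unit intensity — the fluorescence of a single mRNA — is the mean of the
largest-weight component, because in nurse-cell data the dominant
population is single molecules; a weight tie breaks toward the smaller
mean, which encodes the same prior explicitly. Copy number is
intensity/unit (raw and nearest-integer, floored at 0), and molar
concentration is `copies / (N_A · volume)` with volumes taken per granule
when measured, or from a cohort mean otherwise. The protein branch fits an
OLS calibration line through a fluorophore dilution ladder and inverts it;
predictions outside the fitted concentration range are flagged as
extrapolated rather than rejected. Saturated (clipped) intensities are the
user's responsibility; photon-counting acquisition avoids them at the
source.

## Colocalization

The statistic is object-based: the observed fraction of reference objects
whose nearest target centroid lies within the window (default 250 nm, the
confocal resolution limit — a centroid criterion, hence centroid matching
rather than overlap), minus the mean of a randomization null. The null
re-places only the target channel — uniformly over the confinement mask
(uniform voxel choice plus sub-voxel jitter), with replacement and no
exclusion between randomized objects — and recomputes the observed fraction
R times (default 100). The full null vector, its SD, and a one-sided
exceedance proportion are returned for re-analysis; the frequency is
`observed − null_mean`.

In sparse fields the null mean approaches the Poisson void probability
`1 − exp(−λ·V_window)`, which the tests verify. In crowded fields chance
matches are common and the frequency *underestimates* the true partnered
fraction — a property, not a bug, and the dense-field tests confirm the
bias is always downward. The estimator's residual bias at moderate density
is of order `f·p_chance`; the recovery tests size their fields so this
stays within ±0.02 at n_ref = 500.

## AP polarity

`center_of_mass_displacement()` compares the intensity-weighted centre of
mass of the background-subtracted channel (negative weights clipped at 0)
with the geometric — unweighted — centre of the cell mask, along a
user-supplied AP axis: images carry no intrinsic polarity, so the axis and
its posterior orientation are required inputs, never inferred. Both the raw
displacement (nm) and the displacement normalized by the mask's bounding
extent along the axis are reported, since normalization conventions differ
between studies; the normalized value lies in [−0.5, +0.5] with posterior
positive. Background defaults to a user constant. `compare_groups()` is a
thin reporting wrapper over the unpaired two-tailed t-test (means, SDs, t,
p), flagged as routine statistics; exact zero-variance separation is
reported as an error rather than an infinite t.

## Pipeline, I/O and provenance

Images travel as multi-page 32-bit-float TIFF with a JSON sidecar carrying
axes, shape, channel names and voxel size, plus a power-of-two intensity
scale and integer offset (TIFF float samples live in [0, 1]; the
power-of-two scale makes the round trip exact for integer photon counts).
Reading a TIFF with neither sidecar nor an explicit `voxel_size` is an
error — physical calibration is never silently defaulted. Ground truth,
mixture models, calibration curves and colocalization results serialize to
JSON; granule records and FRAP traces to CSV.

`run_pipeline()` executes simulate → threshold → label → measure from a
strictly validated config (unknown keys rejected by name), emits a
provenance record (config fingerprint, seed, package version, thresholds
and connectivity actually used, stage timings), and is bit-identical under
a fixed config and seed. A failing stage halts the run naming the stage.
The package's interface is its functions plus this config-driven driver; a
shell wrapper would add nothing for an analysis library used from R.

## Problem sizes used in validation

The test-suite fields are sized to exercise the estimators' operating
regimes while staying lightweight: 50-granule 3D fields of 40 × 200 × 200
voxels at 100 nm for segmentation recovery; single granules at 40 nm voxels
for shape work; FRAP grids of 18 parameter cells × 3 noise replicates at
600 post-bleach frames; mixtures of 3000–5000 spots; colocalization nulls
of R = 100–500 with 200–500 objects per channel; 10⁴-draw diameter cohorts.
These are the package's chosen validation conditions and are all generated
in code at test time.

## Known limitations

- Aspect ratios are apparent (PSF-convolved) sizes; no deconvolution or
  depletion-power modeling is attempted, so anisotropic optics will bias
  ratios exactly as they do in real measurements.
- The FRAP model is a single exponential; diffusion-reaction kinetics,
  bleach-profile corrections and multi-exponential model selection are out
  of scope.
- The Gaussian mixture assumes intensity noise roughly symmetric about
  `k × unit`; strongly skewed single-spot intensity distributions would
  need a different component family.
- The colocalization null assumes the target channel is free to occupy the
  whole confinement mask; if real targets are sterically excluded from
  sub-regions, the null overestimates chance matching.
- Touching granules are not split; counts in dense fields are counts of
  connected clumps.
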