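---
title: "Quantifying ventilation inhomogeneity with sliding-kernel CV maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ventilation inhomogeneity with sliding-kernel CV maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the score

Chronic obstructive pulmonary disease (COPD) reduces ventilation regionally:
in a ventilation SPECT image of an inhaled \(^{99m}\)Tc aerosol, diseased
regions deposit less tracer, so disease shows up as *inhomogeneity* of the
reconstructed activity distribution rather than as a focal lesion a reader
could point at. `lungcv` implements a global score for that inhomogeneity.

The score is built in four steps:

1. **CV matrix.** A cubic kernel (side 3 cm by default) steps voxel-by-voxel
   through the reconstructed volume. At each voxel of the analysis lung the
   local coefficient of variance
   \(\mathrm{CV} = 100\,\sigma/\mu\) (sample SD over mean, in percent) is
   computed from the in-lung voxels inside the kernel and stored at the
   kernel centre.
2. **Frequency function.** The CV values are histogrammed into 1 %-wide
   bins, normalised so the area under the curve is 100 %.
3. **Threshold \(CV_T\).** The modal value (peak-bin midpoint) of the *mean*
   frequency function of a healthy reference group. The threshold is always
   recomputed from the reference group at hand — healthy lungs imaged on a
   different chain have a different noise floor, and the score is only
   meaningful relative to it.
4. **Score.** \(AUC(CV_T)\): the percentage of all valid CV values strictly
   greater than \(CV_T\). A perfectly homogeneous, noise-free lung scores
   0 %; a lung whose CV distribution sits entirely above the healthy mode
   scores 100 %. A healthy subject scores about 50 % by construction,
   because roughly half of a unimodal distribution lies above its mode.

```{r}
library(lungcv)

plan <- experiment_plan(
  distributions = copd_distributions()[c("uniform", "1cm_50pct_10_even")],
  realisations = 20L, seed = 1L)
result <- run_experiment(plan)
result$cvt                      # modal threshold of the normal group
result$summaries                # mean AUC(CV_T) per distribution
result$comparisons              # Mann-Whitney U versus the normal group
```

## Why a threshold at the healthy mode

Counting only the CV mass *above* the healthy mode makes the score
one-sided on purpose: noise pushes CV values up everywhere, but ventilation
defects add a right tail. Using the mode (rather than the mean or median)
makes the reference robust against that same right tail in the reference
group. With 1 %-wide bins the peak bin \([k, k+1)\) yields
\(CV_T = k + 0.5\). The score uses a strict `>` on the raw CV values, not
on the binned curve, so no bin-edge convention can move it by a whole bin.

## The simulation chain

The package reproduces the simulated discrimination experiment end to end.
Every stage is deliberately idealised but *self-consistent*: what the
projector does, the reconstruction assumes, so there are no uncorrected
mismatches that would masquerade as lung signal.

**Phantom** (`phantom_spec()`, `build_lung_mask()`): two ellipsoid-like lung
fields with flattened medial faces, a mediastinal gap and a Gaussian
diaphragm dome, rescaled by bisection to a 4.2 L total lung volume (a
typical elderly male). Anatomical fidelity beyond volume, two-lobed
topology and an apex-base axis is irrelevant to the analysis method, which
never looks at shape.

**Lesions** (`lesion_spec()`, `place_lesions()`): COPD-like ventilation
defects are non-overlapping spheres (diameter 1-2 cm) at 0-50 % of the
surrounding activity, occupying 10-48 % of the lung. Centres are drawn by
seeded rejection sampling, uniform over the lung, up to 30 % occupancy;
above that random packing jams (hard spheres jam near 38 %), so a randomly
thinned, randomly offset face-centred-cubic lattice (packing limit 74 %) is
used instead. Clustered placement packs *discrete* lesions by rejection
sampling into the smallest spherical region around the medial hilum
landmarks that holds the requested occupancy, growing the region when
packing stalls; a denser lattice fill was rejected because it merges the
lesions into an internally homogeneous blob that no longer behaves like a
collection of lesions (only its surface would carry CV signal). With the
discrete cluster, the clustered and even variants of the same lesion load
score nearly identically, as they should. Achieved occupancy is tracked on
the rasterised voxels (a voxel is lesion iff its centre falls in a sphere)
and is kept within 0.5 percentage points of the request.

**Projector** (`forward_project()`): rotate-and-sum parallel beam, with
optional attenuation line integrals and a single in-plane Gaussian system
blur of FWHM 12 mm applied in the projection domain — the middle of the
1-1.5 cm resolution range of a LEHR-collimated clinical system. The
in-plane rotation is an exact quarter-turn permutation composed with a
three-shear (Paeth) residual rotation; each shear is doubly stochastic away
from the field-of-view border, so the rotation conserves every voxel's
counts exactly and maps uniform fields to uniform fields — no interpolation
ripple in the projections and no count leakage between views. (A bilinear
resampling rotation loses up to 7 % of a point source at oblique angles;
its transpose conserves counts but dithers them.) There is no Monte Carlo
photon transport, no scatter and no depth-dependent response; scatter is
neither simulated nor corrected, which keeps the chain consistent at desk
scale.

**Counts and noise** (`scale_to_counts()`, `poisson_realise()`): the
noiseless projections are rescaled to a clinical total-count budget and
each acquisition is imitated by an independent Poisson realisation. The
reference budget is 3.635e6 counts over 128 angles; when fewer angles are
simulated the budget scales proportionally, which preserves the
per-projection count density. On the default desk-scale chain the
high-count lung pixels hold roughly 50 counts, i.e. a pixel-level CV of
about 14 % — the clinical noise regime.

**Reconstruction** (`osem()`, `butterworth3d()`): basic OSEM (multiplicative
EM updates per subset, stride subset assignment, bit-reversed subset order,
uniform start inside the field of view), 10 iterations of 16 subsets, then
a 3D Butterworth post-filter, cut-off 0.5 cm\(^{-1}\), order 3
(\(|H(f)|=(1+(f/f_c)^{2n})^{-1/2}\), gain \(1/\sqrt2\) at cut-off, DC
preserved). The filter is applied to the volume, not per slice, to avoid
slice-direction anisotropy. Attenuation correction is available (using the
projector's own line-integral model) but off by default, matching data
simulated without attenuation. End to end, a point source reconstructs
with a FWHM of about 14 mm on the desk-scale grid.

**Segmentation** (`lung_from_reconstruction()`, `lung_from_ct()`, `peel()`):
for simulations, voxels strictly above half the maximum of the noiseless
normal reconstruction; for human data, attenuation below 0.12 cm\(^{-1}\)
inside the body (border-touching air components discarded, two largest
components kept). One voxel-wide layer is then peeled off by 6-connected
erosion: the blurred lung edge produces high CV values that reflect the
boundary, not ventilation. On the desk-scale phantom the peel removes about
22 % of the lung. Both the kernel centres and the voxels entering the
kernel statistics are restricted to the peeled lung; the alternative
reading (statistics over the full lung, centres in the peeled lung) is
available via the `centres` argument of `cv_kernel()` but pushes the
healthy self-score far above the ~50 % regime, because near-edge kernels
then inherit the edge gradient.

**Statistics** (`mann_whitney_u()`, `group_summary()`): groups of
per-realisation AUC scores are compared with a two-tailed Mann-Whitney U
test — exact (via the null distribution of U, or full enumeration when ties
make that necessary and the group sizes allow it), otherwise a
tie-corrected normal approximation — and summarised as mean ± t-based 95 %
confidence half-width. The t convention is pinned by the published cohort:
five healthy AUC values of 52, 75, 57, 72, 71 give 65 % ± 13 %, which a
normal-z interval would misreport as ± 9 %.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| kernel side | 3 | cm | 729 voxels at 3.3 mm pitch; large enough for a stable SD, small enough to stay unimodal |
| bin width | 1 | % CV | the resolution at which \(CV_T\) is defined |
| min in-lung voxels per kernel | 2 | voxels | the logical floor for a sample SD |
| peel layers | 1 | voxels | removes the edge-driven CV tail |
| system blur FWHM | 12 | mm | middle of the 1-1.5 cm clinical resolution range |
| OSEM | 10 x 16 | iterations x subsets | clinical ventilation SPECT practice |
| Butterworth | 0.5 / 3 | cm^-1 / order | clinical post-filter |
| total counts | 3.635e6 x angles/128 | counts | clinical budget at preserved count density |
| realisations | 20 | - | the simulated study design |

## Desk-scale choices and what they cost

The default experiment runs a 64^3 grid at 6.6 mm pitch with 64 angles —
about 3-4 s per OSEM reconstruction, roughly three minutes for a full
two-distribution experiment of 20 + 20 realisations. At this scale the
3 cm kernel spans 5^3 voxels and the peeled lung holds about 11,000 CV
centres (a clinical-scale analysis at 3.3 mm holds about 90,000). Fewer
centres mean noisier per-realisation AUC values, and the unmodelled system
blur (no collimator-response compensation in OSEM) costs lesion contrast
relative to a compensated clinical chain. Both effects shrink the gap
between the normal group and the *subtlest* lesioned distribution (1 cm
lesions at 50 % activity in 10 % of the lung — a 5 % total ventilation
reduction that is invisible to the eye in the reconstruction); the
Mann-Whitney p-value for that case lands near 10^-3 to 10^-4 at desk scale
depending on the seed, while every other lesioned distribution separates
by far more and the full ordering (normal below all eight lesioned rows,
scores non-decreasing in lesion load and contrast) is preserved.

One desk-scale caveat deserves emphasis: the healthy self-score. With
~11,000 correlated CV centres the normal CV distribution is nearly
symmetric but only ~2 CV-percent wide, so the fraction of it above the
modal-bin midpoint is exquisitely sensitive to where the distribution's
centre falls *within* the 1 %-wide modal bin — a sub-bin alignment effect
worth up to ±10 AUC points. On this chain the healthy group scores a mean
self-AUC near 60 % rather than the ~52 % a clinical-width CV distribution
(4-5 % wide) yields, where the same alignment effect is halved. The score
remains internally consistent: all group *comparisons* are unaffected,
because every group shares the same CV_T.

Respiratory motion is modelled as a conservative axial displacement
time-average with linearly depth-dependent amplitude (basal > apical),
`apply_motion_blur()`. It is off by default in `experiment_plan()`: it adds
a basal high-CV band to *every* group and thus only blurs the group
contrast the experiment measures; it is exercised separately, where it
reproduces the expected basal-over-apical CV excess in the normal lung.
Heartbeat motion is not modelled at all — it has no reported effect on this
analysis.

## Numerical conventions and degenerate inputs

* Sample SD (n-1) in the CV; at hundreds of voxels per kernel the
  difference from the population SD is far below every tolerance.
* Kernel side in voxels is rounded to the nearest odd integer, so a 3 cm
  kernel is 9 voxels at both 3.3 and 3.45 mm pitch, and 5 voxels at 6.6 mm.
* Kernels with fewer than 2 in-lung voxels or non-positive mean are
  invalid, not zero. An empty CV matrix is an error, never a silent 0 %.
* OSEM guards zero forward projections (ratio set to 0 where both model and
  data vanish) and masks voxels with zero sensitivity out of the update.
* The bisection that sizes the lung stops at 0.5 % volume error and the
  phantom refuses grids whose extent cannot hold the requested volume.
* All randomness (placement, Poisson draws) flows from explicit integer
  seeds; per-realisation seeds are derived from the master seed and the
  distribution label, and recorded in the output.

## Known limitations

* The phantom is geometric, not anthropomorphic; peel fractions and
  absolute CV levels are geometry-specific and are not claims about any
  particular anatomy.
* No scatter, no depth-dependent collimator response, no non-circular
  orbit: the chain reproduces the noise-and-resolution *regime* of a
  clinical system, not its point-spread function.
* Passing the simulated tests shows the score separates homogeneous from
  lesioned activity under clinical-like counting noise; it does not show
  robustness to hot spots, gravity gradients, inhalation-depth variation or
  tracer-dose differences, which dominate real human variability.
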