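---
title: "Staging pork from hyperspectral cubes: models, parameters and design choices"
author: "porkHSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging pork from hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porkHSI)
```

## The problem

Pork stored chilled after slaughter moves through three commercially
meaningful phases. During *rigor mortis* (roughly the first two days),
glycolysis acidifies the muscle — pH reaches its minimum — while irreversible
actin–myosin binding drives shear force (WBSF, the force needed to cut a
cooked core across the fibre direction) to its maximum. During *aging*,
endogenous proteases fragment the myofibrils: the myofibrillar fragmentation
index (MFI) climbs, WBSF falls, and the meat tenderises until the shear force
settles at a basic-hardness plateau. Eventually protein decomposition and
microbial growth push the meat into *spoilage*, indicated by total volatile
basic nitrogen (TVB-N) above 20 mg/100 g or a total viable count (TVC) above
7 log10 CFU/g — strict thresholds, applied with precedence over any other
classification.

Destructive assays can stage a sample but not a pixel. Visible/short-NIR
hyperspectral imaging records a full reflectance spectrum at every pixel, so
a classifier trained on whole-sample spectra can be applied pixel by pixel to
draw an *aging map*: where on the cut surface the meat is still in rigor,
where it has aged, and where spoilage has begun. Spoilage advances inward
from the sample edges, which is exactly the structure such maps expose.

## The pipeline

1. **Segmentation.** The sample is separated from the dark background by
   thresholding an intensity image (mean reflectance over bands by default).
   The threshold maximises between-class variance over the empirical
   histogram — Otsu's criterion, computed by exact exhaustive scan over every
   cut point between consecutive distinct values rather than over a binned
   histogram, so the optimum is not quantised. The largest connected
   foreground component is kept (`EBImage::bwlabel`); smaller specks are
   discarded. A fixed-threshold override exists for scenes where the
   histogram rule is inappropriate.

2. **Spectrum extraction.** The mean spectrum over the region of interest is
   the sample's calibration spectrum; per-pixel spectra drive the maps. Both
   views are consistent by construction: the ROI mean equals the mean over
   the per-pixel spectra to floating precision.

3. **Wavelet compression.** Each 438-band spectrum (400–1100 nm) is run
   through a multilevel discrete wavelet transform that recurses on the
   approximation branch only. With half-point symmetric boundary extension
   each step maps a length-*n* signal to approximation and detail vectors of
   length floor((*n* + *L* − 1)/2), *L* the filter length, so db5 (*L* = 10)
   produces detail lengths 223, 116, 62, 35, 22, 15 and 12 at levels 1–7.
   The level-*k* feature vector is the concatenation [cA_k, cD_k] — 70
   values at level 4. Approximations keep the spectral shape (they get
   smoother with depth); the mid-level details carry the localized
   differences that distinguish rigor from aged meat, whose gross spectral
   curves are nearly identical.

4. **Classification.** A radial-basis SVM (one-vs-one multi-class voting,
   libsvm via e1071) is trained on z-score-standardised features; the scaler
   is fitted on calibration data only. The penalty C and kernel width sigma
   (gamma = 1/(2 sigma^2)) are tuned by global-best particle swarm
   optimisation against 5-fold cross-validated accuracy on the calibration
   set.

5. **Mapping.** Every ROI pixel's spectrum is decomposed at the model's
   wavelet/level and classified; maps render rigor green, aged blue, spoiled
   red, background black. A monitoring wrapper tracks per-day stage
   fractions and raises an alarm on the first day the spoiled fraction
   exceeds a configurable threshold (default 5% of ROI).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `wavelet`, `level` | `"db5"`, 4 | Feature family and depth; db5/level-4 balances compression against detail retention |
| `mode` | `"symmetric"` | Boundary policy; the only standard mode whose length bookkeeping yields 223…12 from 438 bands. `"periodization"` is provided for energy-exact analyses |
| `plateau_rel_tol` | 0.05 | Relative tolerance that operationalises "WBSF no longer significantly reduced" and the rigor pH/WBSF windows |
| PSO settings | swarm 20, 30 iterations, inertia 0.72, c1 = c2 = 1.49 | Standard constricted-PSO values; search box C in [1e-2, 1e4], sigma in [1e-3, 1e2], both in log10 space |
| `n_train`/`n_test` | 66/34 | Calibration/verification sizes for the 100-sample design, stratified by largest-remainder apportionment |
| `alarm_threshold` | 5% | Spoiled-fraction level that flags a sample for removal |
| `dim_cap` | 300 | Feature widths above this are reported as infeasible in the level sweep (raw 438-band spectra and the 446-wide level-1 features) rather than fitted |

## The synthetic-data generator

No public hyperspectral pork dataset exists for this staging problem, so the
package ships a generator that reproduces the *structure* of the real
measurements and serves as ground truth for every downstream test.

**Spectra.** A shared smooth base curve (sigmoidal red-edge rise, paired
oxymyoglobin absorption dips at 545/575 nm, a water dip near 970 nm)
underlies all three classes. Spoiled meat adds a fixed broad +0.08 visible
offset tapering into the NIR, making its visible-range mean the highest.
Rigor and aged differ only by localized detail — narrow (8 nm) alternating
peaks plus a slight NIR depression for the later stage — scaled by
`class_separation` (default 0.04 reflectance), so the discriminative signal
lives at detail scales, and the deepest decompositions, which smooth those
scales away, classify worse than mid-level ones. Noise is band-correlated:
iid Gaussian filtered with a Gaussian kernel (half-width 2 bands) whose
weights are normalised to unit energy, leaving each band with marginal
standard deviation `noise_sd` (default 0.01 reflectance). Real reflectance
noise is band-correlated; white noise would make the detail channels
unrealistically noisy.

**Cubes.** An axis-aligned ellipse (semi-axes 0.4 of each image dimension)
on a constant 0.02-reflectance background with small noise — guaranteeing
the bimodal histogram the segmenter expects. Within the ellipse an edge
annulus of relative radial width `edge_fraction` carries the more advanced
stage, emulating edge-first aging and spoilage.

**Trajectories.** Smooth parametric curves per animal over 12 storage days:
a cubic pH dip to day 2 followed by a linear rise that accelerates
quadratically once spoilage begins; WBSF peaking at day 2 (day 1 at 95.5–98.5%
of the peak) then decaying exponentially to a basic-hardness plateau; a
saturating-exponential MFI rise; logistic TVB-N growth; and TVC with an
early dip through day 2 before logistic microbial growth. Between-animal
variation enters only through the curve parameters (levels, rates, onset
days), never as additive observation noise — so the canonical shapes hold
for every draw, and spoilage onset still differs across animals. A
15-animal cohort yields roughly 30 rigor, 55 aged and 35 spoiled sample-days
with the rest transitional, from which the fixed 30/40/30 modelling design
is drawn.

What the generator does *not* emulate: illumination gradients, specular
highlights, instrument striping, the 1000–2200 nm NIR range, multi-sample
scenes, or within-class biological covariance beyond the smooth noise model.
Passing tests therefore demonstrate that the pipeline's machinery is correct
and well-calibrated on data with the documented structure — not that the
reported accuracies transfer to any particular instrument's cubes.

## Numerical choices

- **Boundary extension.** Half-point symmetric extension is the default
  because it is the standard toolbox convention whose coefficient counts
  reproduce the 223/116/62/35/22/15/12 cascade; periodization (count
  ceil(n/2)) is the mode under which orthogonal banks conserve energy
  exactly, and is used for the Parseval checks.
- **The dmey filter.** The discrete Meyer wavelet is by definition an FIR
  truncation of an ideal (infinite) conjugate mirror filter. The common
  62- and 102-tap truncations leave perfect-reconstruction defects of about
  5e-3 and 4e-6 respectively — far above the 1e-8 round-trip fidelity this
  package commits to. porkHSI therefore synthesises its dmey bank at load
  time by frequency-sampling the ideal Meyer response and truncating at 402
  taps, where the defect is about 4e-9. The trade-off is depth: a 402-tap
  filter supports fewer decomposition levels on short signals.
- **"db" means db5.** The Daubechies family member is pinned to db5
  (filter length 10), the variant that extracts the stage-discriminating
  detail best.
- **Feature ordering.** [cA_k, cD_k], approximation first; intermediate
  detail vectors cD_1..cD_{k-1} are not included (the level-k feature
  dimension is exactly 2 x len(cA_k)). No detail-coefficient thresholding or
  denoising is applied before modelling.
- **Reconstruction trimming.** The inverse cascade trims each step to the
  recorded forward input length (symmetric-mode steps on odd lengths
  naturally reconstruct one sample long).
- **Rigor/aged labelling.** "Lowest pH and highest WBSF" is windowed with
  `plateau_rel_tol` rather than taken as single argmin/argmax days, because
  exact extrema are fragile under measurement noise; "no longer
  significantly reduced" is a day-over-day relative WBSF decrease below the
  same tolerance, since no statistical test is prescribed for single
  trajectories.
- **Plate-count formula.** The TVC aggregation uses the (n1 − n2)
  denominator exactly as specified for this assay variant; note that the
  national-standard weighted form uses (n1 + 0.1 n2) — consumers comparing
  against that convention should rescale.
- **Ties and degenerate inputs.** The Otsu scan breaks ties toward the
  lower cut; constant images are rejected as degenerate; empty masks,
  single-class training sets, and undersized cubes raise early, specific
  errors.
- **Determinism.** Every stochastic step (simulation, splits, folds, swarm)
  takes an explicit integer seed and restores the caller's RNG state;
  identical seeds give bit-identical outputs.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on generated data at
the study's native scale where that is cheap (100-spectrum cohorts, 66/34
splits, ten split seeds, the six-row level sweep) and at reduced spatial
scale where it is not (64 x 64 hypercubes, twenty seeds for the
segmentation/mapping sweeps; 24 x 24 cubes in unit tests). These sizes were
chosen so the whole suite exercises every stage end-to-end in a few minutes
on a single core.

## Known limitations

- The mapping from a real instrument's 512 bands (308–1105 nm) onto the
  438-band 400–1100 nm analysis grid is instrument-specific; `cropBands`
  makes the window explicit but resampling onto the canonical grid is the
  user's responsibility, and models refuse cubes whose grid does not match
  their fingerprint.
- No reflectance calibration (white/dark reference) stage is included;
  cubes are assumed pre-calibrated.
- Maps receive no spatial post-processing (no median filtering); noisy
  per-pixel predictions are rendered as-is. A 5-band moving-average spectral
  smoother is available behind `smooth_bands` for noisy cubes.
- Reported accuracies on synthetic cohorts characterise the machinery, not
  any real instrument or cut; transitional samples are excluded from
  modelling by design, so the classifier is never asked to place a sample
  between stages.
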