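---
title: "Methods: registration, cell mapping, and photometry integration in thalint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, cell mapping, and photometry integration in thalint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalint)
```

# Scope and data model

`thalint` implements two linked analyses of basal-ganglia/cerebellar
convergence in the motor thalamus: registration of annotated serial
coronal sections to a reference atlas with brain-wide cell mapping, and
multi-site fiber-photometry preprocessing with a linear integration model
tested against a time-shift shuffle null. Because the corresponding animal
data are not packaged, every input class has a seeded synthetic generator
with known ground truth; the test suite and the acceptance script assess
the pipeline by recovery of that truth and by agreement with independent
brute-force oracles, not by re-deriving any published cohort statistic.

All spatial interfaces use physical micrometers in an (ap, dv, ml) frame:
AP increases posteriorly, DV ventrally, ML is signed with the midline at
0. A section index `k` corresponds to AP = `k * section_um`
(40 um default, the slice thickness used for whole-brain mapping).
Annotation tables (fiducials, bounding boxes, cells) and image pitch
metadata (0.454 um/px widefield default) do all pixel-to-physical
conversion at I/O; no algorithm ever sees pixels.

# The registration chain

## Model

An experimental brain is modeled as the atlas pushed through an affine
map plus per-section translational drift. The fitted chain mirrors that
structure in six ordered steps: (1) a least-squares affine over the four
non-SCO midline fiducials; (2) an AP shear `ap' = ap + s*ml` fitted on
the two lateral fiducial pairs; (3) a translation anchoring both volumes
at the SCO, which becomes the origin; (4) an AP scale matching the AP
length containing a cumulative bounding-box volume quantile (0.99)
anterior of the SCO; (5–6) ML/DV scales matching mean bounding-box width
and height within ±1 mm of the SCO; then a per-slice (ml, dv)
translation moving the transformed volume's dorsomedial box corner onto
each annotated section's corner. Cell coordinates go to atlas space
through the slice-specific inverse.

The assumptions are those of the model family: the global deformation is
affine (no diffeomorphic warping), left/right asymmetry is a pure AP
shear, and serial-alignment drift is translational within a section —
which is why the per-slice correction has exactly two degrees of freedom
per section.

## Identifiability of the decomposition

The six-step decomposition is not unique. The midline affine has six
degrees of freedom fitted on four (ap, dv) points, so any AP/DV scaling
present in the ground truth is absorbed into step 1, and the fitted shear
carries the AP-scale-composed asymmetry coefficient. Recovery is
therefore assessed on what is identifiable: the composed forward matrix,
point-level mapping error, and the ML scale (which no earlier step can
absorb; it is recovered to ~0.1% in the shipped tests). This is a
property of the algorithm itself, not of the implementation.

## Numerical choices

* **Step-1 axes.** The fitted linear map takes (ap, dv) inputs because
  midline fiducials vary only in those axes. `axes_mode = "ap_dv"`
  (default) refits AP and DV and passes ML through; the literal
  `"ap_ml"` mode refits AP and ML and passes DV through. Both are
  exposed because the intended output-axis pair is genuinely ambiguous;
  the default is the midsagittal-plane reading, under which the four
  in-plane points constrain the in-plane map.
* **Volume quantile.** The 99% rule is read as a cumulative-volume
  quantile length along AP, integrated at 1 um steps from the anterior
  pole to the SCO — the only reading that yields one scalar length per
  volume. `volume_fraction = 1` degrades gracefully to the full-extent
  ratio.
* **Boxes under affines.** Bounding boxes transform by mapping the eight
  corners of each 40 um slab and taking axis-aligned extents. Both the
  generator and the fitter use the same convention, so the approximation
  (exact for axis-aligned scalings, slightly conservative under shear)
  cancels in recovery tests.
* **Shear fit.** Least squares over both lateral pairs jointly on the
  left-minus-right AP differences; disagreeing pairs are averaged by the
  normal equations.
* **Degenerate inputs.** Collinear midline fiducials, coincident lateral
  points, missing SCO, zero anterior box volume, and empty ±1 mm windows
  all raise errors naming the offending input. Sections outside the
  transformed volume get a zero drift correction with a warning; sections
  without annotations inherit the nearest annotated section's correction
  (drift is smooth).
* **Ties.** Nearest-voxel region assignment rounds half-voxel ties toward
  the larger voxel index, i.e. lexicographically in (ap, dv, ml), for
  determinism.

## Accuracy budget

With the spec-level study conditions (scales 0.8–1.2, |shear| <= 0.06,
translations <= 2 mm, per-slice jitter <= 30 um), the dominant residual
is AP quantization: cells carry AP only through their 40 um section
index, bounding an individual cell's AP error by half a section over the
fitted AP scale. Per-slice jitter is removed exactly by the drift
correction (boxes and cells on a section share the jitter), so the median
3D mapping error in the shipped tests is ~9–13 um — under one 25 um atlas
voxel and under the 20 um acceptance bound.

# Cell scoring and mapping

Sections are level-balanced by a single multiplicative factor each so the
mean background intensity (pixels at or below the 10% intensity quantile
by default; the estimator is configurable) matches the stack mean — never
a local edit. Cell brightness is the mean of the top 20% of pixels in a
25 um circular ROI; ROIs at image edges are clipped to available pixels
(edge behavior is a package choice; the alternative of discarding edge
cells is not taken). Per brain, raw intensities are min–max normalized to
[0, 1] and cells at or below 5% are excluded; if all intensities in a
brain are equal the normalized value is defined as 1 and everything is
retained, since a degenerate brain carries no contrast information to
exclude on.

Distributions divide per-region counts by the per-brain total and then
average across brains (mean ± SEM), with a pooled "other" bucket below 1%
for region-subset tables. Densities bin atlas space into 100 um cubes
anchored at the atlas origin (so bin edges coincide across brains),
normalize per brain to percentages, and average bins across brains
unweighted.

# Photometry preprocessing

The dF/F order of operations is fixed and pinned by a test: subtract the
background estimate (session mean of the dedicated background channel)
from the 470 nm and 410 nm channels, low-pass both with a 4th-order
Butterworth at 2 Hz, fit `a + b*iso` to the signal channel by least
squares, and output `(sig - fit)/fit`. Consequences worth knowing:

* Filtering is zero-phase (forward–backward with reflection padding, and
  mean-centering so constant traces are exact fixed points); onset-aligned
  analyses at 30 Hz cannot tolerate group delay, and the first/last ~2 s
  of any filtered trace are treated as edge region by the tests.
* Because the isosbestic fit has a free intercept and slope, any shared
  multiplicative exponential bleach is removed to first order, and dF/F
  is invariant to rescaling all channels jointly.
* A fitted isosbestic trace crossing zero makes the division undefined
  and raises an error rather than returning infinities.
* In trial mode, segments of 10 s around movement onset are cut from the
  raw channels and the full preprocessing runs independently per window
  (the per-window reading of the procedure); a session-wide isosbestic
  fit is available by preprocessing the whole trace instead.

Trials are z-scored against a 700 ms pre-movement baseline ending at
onset for the lever task and 500 ms before onset for locomotion (calcium
rises before the velocity-defined onset in locomotion); zero-SD baselines
exclude the trial with a log message. Early/late learning phases default
to days 1–3/8–10 (lever) and 1–2/4–5 (locomotion).

# Integration model and shuffle null

Per subject, 135 s intervals are drawn uniformly within sessions
(20 per subject by default — enough for a stable mean over 10–15 min
sessions; the count is configurable and was not stated by the source
analyses), OLS fits `A*snr + B*dcn + C = thal`, and R² = 1 − SS_res/SS_tot
scores the predicted trace. The control redraws each interval with the
SNr and DCN windows shifted by independent uniform lags in
[−67.5, +67.5] s ("between 0 and ±67.5 s" is read as the symmetric
uniform; excluding a neighborhood of zero is the other reading and is not
taken). Shifted windows always come from the parent session trace —
shifts that would leave the session are redrawn (bounded retries) and
finally clamped, never wrapped, because circular wrapping would splice a
discontinuity into an autocorrelated trace. Intervals may overlap, as
nothing in the sampling rule excludes it. Perfectly collinear regressors
raise an error (non-identifiable).

The shuffle null only has power on autocorrelated signals; for white
traces, observed and shuffled R² distributions coincide (a property test
checks both directions).

# Behavior and evoked currents

Lever pushes: candidate movements are maximal epochs above half the push
threshold, merged across gaps under 200 ms; an epoch counts as a push
only when its peak strictly exceeds 1 mm and as successful at or above
the 5 mm reward threshold. The onset walks back from the epoch start to
the last sample at or below 10% of the push threshold (bounded at
0.5 s). The half-threshold gate exists because the 10% criterion alone
is incompatible with noise immunity: broadband noise above 0.1 mm would
suppress every quiet period while never producing a false push, so
detection gates at 0.5 mm and only the onset refinement uses the 10%
level. Counts and flags are invariant to added sub-threshold noise below
half the push threshold; clean-trace onsets are unchanged.

Velocity-based movement onsets require ≥0.5 s below threshold before a
crossing. Running bouts are supra-threshold epochs (1 cm/s, ≥1 s, gaps
≤0.5 s merged); these three constants are explicit configuration, stated
nowhere in the source analyses. Optogenetic windows are a pure function
of laser onset/offset: baseline [on−120, on], inhibition [on+60, on+180],
post [off+60, off+180] seconds. Inclusion rules: photometry keeps
subjects averaging ≥10 pushes/session; silencing keeps sessions with
≥2 baseline pushes/min and selects the higher-baseline of a subject's two
sessions.

Evoked amplitudes subtract the mean current over the 50 ms before laser
onset from the largest-deviation sample within 100 ms after onset (the
search window is a package choice; stimulus pulses are 1–50 ms). Cells
classify as receiving DCN input at inward (negative) amplitudes ≥25 pA in
magnitude and SNr input at outward amplitudes ≥100 pA; the
cross-activation check flags an inward −70 mV response as artifactual
when the same 450 nm stimulus drives an outward current ≥100 pA at
+10 mV (the threshold reuses the outward criterion; the source comparison
states no cutoff). Classification operates on raw amplitudes with the
flag carried alongside, since whether the criteria apply to corrected
amplitudes is unstated.

# What the generators emulate — and what they do not

* **Mini atlas.** Axis-aligned ellipsoidal "nuclei" (stand-in acronyms
  VM, VAL, ...) inside a bounding-box volume whose width/height profiles
  taper away from the center, with the five midline and four lateral
  fiducials placed programmatically on the voxel grid. Region radii are a
  few hundred micrometers at the default 6 x 4 x 4 mm extent — the scale
  of real motor-thalamic nuclei. Unlike real atlases, voxels between
  regions are unlabeled; recovery tests therefore score distributions
  over cells assigned to labeled regions, since "lost to background" is
  an artifact of the toy geometry that a fully-labeled atlas cannot
  produce. Default pitch is 25 um (10 um is supported; registration
  accuracy is pitch-independent, only assignment granularity changes).
* **Brains.** The atlas pushed through a ground-truth chain drawn from
  the same family the fitter assumes, with Gaussian per-slice jitter.
  Real deformations are not exactly affine; passing tests show the chain
  is recovered when the model holds, not that an affine suffices for
  arbitrary histology.
* **Photometry.** SNr/DCN sources are Poisson event trains (0.2 events/s)
  convolved with a 50 ms-rise/1 s-decay kernel — autocorrelated, which is
  what gives the shuffle null its power. The thalamus ideal trace is an
  exact linear mixture plus Gaussian noise; channels share a single
  exponential bleach (tau 600 s) and an additive background, and the
  410 nm channel carries the artifacts but no transients. The noise
  spectrum of real recordings is not characterized anywhere; Gaussian
  noise plus exponential bleach is a stated assumption, not a fit, so
  dF/F performance on real hemodynamic/motion artifacts is untested.
* **Behavior.** Half-sine lever pulses and trapezoidal running bouts with
  exact, non-overlapping onsets; no postural noise or partial pushes
  beyond what the noise-invariance tests inject.

# Problem sizes and reproducibility

The shipped tests and `scripts/acceptance.R` run at deliberately compact
sizes chosen to exercise every claim while keeping a full run fast on one
CPU: a 240 x 160 x 160-voxel atlas at 25 um, 10–20 synthetic brains of
150–1000 cells for registration properties, 10^4-cell instances for the
enumeration oracles, 300–900 s photometry sessions at 30 Hz with up to
20 intervals per subject, 30–100 seeded runs for the shuffle-separation
rate, and the full ±500 pA grid at 1 pA steps for the classification
truth table. All randomness flows from explicit integer seeds; the
end-to-end `run_all()` writes byte-identical tables for identical
configuration and seed, plus a manifest (config hash, seeds, package
version) sufficient to reproduce any table.

# Known limitations

Registration is strictly affine-plus-per-slice-translation; nonlinear
warps, section tears and missing sections are out of scope. The per-slice
correction assumes the annotated dorsomedial corner is reliable. Region
assignment trusts the atlas labels at the queried pitch. The integration
model is instantaneous and linear — no lags, interactions or
nonlinearities — by design, matching the analysis it implements. The
significance machinery (paired tests, ANOVA) is intentionally left to
standard tools; the package emits the per-subject summary tables those
tools consume.
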