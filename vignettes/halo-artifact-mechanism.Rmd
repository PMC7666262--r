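---
title: "How a urinary catheter breaks tail-fitted scatter correction: the model behind halosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How a urinary catheter breaks tail-fitted scatter correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

FDG excreted through an indwelling urinary catheter is intensely radioactive
(50 times the body concentration in the layouts simulated here) and lies
*outside* the patient. Clinical scatter correction — tail-fitted single-scatter
simulation (TF-SSS) — scales an analytic single-scatter estimate so that it
matches the measured data in the "tail": sinogram bins classified, from the
attenuation map (μ-map), as containing scatter only. If the μ-map does not know
about material that is emitting during the PET acquisition, those bins land in
the tail, the fitted scale factor absorbs their (unscattered) counts, the
scatter estimate is inflated, and the iterative reconstruction — which cannot
produce negative voxels — drives the surrounding body to zero: a photopenic
*halo* that can mask real tumours. Two mismatch routes are simulated:

* **urine shift** — urine moved between the CT and the PET acquisition, so a
  catheter segment emits without appearing in the μ-map at any voxel size;
* **tube curve** — a catheter coiled into an arc vanishes from the *coarse*
  (4 mm) μ-map through partial-volume averaging while remaining visible at
  2 mm.

A Monte-Carlo-scaled correction (MC-SSS) needs only the global ratio of
scattered to true-plus-scattered events, no tail, and is immune to both.

## The pipeline

`run_experiment()` chains the package's modules:

1. `make_phantom()` renders an elliptical water cylinder (semi-axes
   15 × 10 cm, 24 cm long, 3.0 kBq/mL ≡ SUV 1.0) and a 9-mm outer / 7-mm inner
   vinyl-chloride catheter (150 kBq/mL where urine is present) on a 1-mm
   isotropic truth grid, together with *two* attenuation truths: what the CT
   saw and what was physically present during PET. The fine grid matters: the
   axial partial volume of the obliquely curving tube is only sampled
   correctly when several truth planes fall inside one μ-map voxel.
2. `simulate_trues()` produces noiseless expected true coincidences with a
   Joseph-type parallel-beam projector (2-mm data-generation grid, distinct
   from the 4-mm reconstruction grid), attenuated by the *physically present*
   material.
3. `mc_transport()` generates the ground-truth scatter: in-plane photon-pair
   transport with Woodcock tracking, Klein–Nishina Compton sampling,
   energy-dependent attenuation, photoelectric absorption, Gaussian energy
   blur and a 460–665 keV window, up to second-order scatter. Smoothed and
   anchored to the analytic trues, it completes the "measured" prompts.
4. `sss_estimate()` is the analytic single-scatter simulation on a 20-mm
   scatter-point grid; `tail_mask()` + `tail_fit_scale()` implement TF-SSS;
   `mc_scale()` implements MC-SSS from the transport's scatter fraction.
5. `osem()` reconstructs (3 iterations × 11 subsets, 144 × 144 at 4 mm) with
   attenuation and the additive scatter term; `calibrate_suv()` divides by the
   known 3.0 kBq/mL reference — calibration is analytic, never fitted to the
   data.
6. `detect_halo()` applies the two-step rule (runs of ≥ 3 near-zero voxels in
   the corrected image that are positive in the uncorrected one) and
   `suv_per_slice()` produces the per-slice SUV curves.

## Model assumptions and their consequences

**2.5-D geometry.** Every 4-mm slice is an independent 2-D parallel-beam
problem. This keeps a full study on one CPU in minutes and retains the
artifact mechanism, which is in-plane. It discards oblique lines of response;
consequences are discussed under the tail mask below.

**Axial acceptance of scattered photons** (`scatter_axial_acceptance`,
default 0.5). An in-plane-confined transport would count *every* scattered
photon as detectable, which drives the scatter fraction of a 20-cm water
cylinder to ≈ 0.43 — far above the ≈ 0.25–0.35 clinical scanners measure in
this energy window — and doubles the weight of broad-tailed multiple scatter.
In reality a Compton deflection has an out-of-plane component and the photon
usually leaves the slice's axial acceptance. Each scatter event therefore
survives with probability 0.5 (multiples are suppressed quadratically, as each
leg can escape). With the default, the simulated scatter fraction is ≈ 0.24,
and the same factor enters `sss_estimate()` so the analytic and Monte-Carlo
scatter models remain mutually consistent. Sensitivity: raising the value
toward 1 inflates the scatter burden and degrades tail-fit accuracy for
*matched* data — it exaggerates, rather than creates, the mismatch artifact.

**Tail mask calibration.** The clinical mask thresholds the μ-map just below
the catheter material's attenuation (a ≈ 2.4 % margin). That knife edge is the
mechanism, and the package reproduces it in the image domain: the default
threshold is 0.0935 cm⁻¹, 97 % of water's 0.096 cm⁻¹ at 511 keV, with a mild
3-mm in-plane smoothing of the μ-map (`prepare_mumap()`; CT-derived maps are
processed per slice, and heavier smoothing was found to make the peak μ of a
tube *orientation-independent* — a mass-conservation effect — which destroys
the straight-versus-curved distinction entirely). Under these defaults:

* a straight, grid-aligned catheter always contains a fully-interior 4-mm
  voxel at full μ → visible, correctly excluded from the tail (the urine-shift
  CT+ segments and the skin-attached layout stay artifact-free);
* the obliquely curving catheter rarely contains a fully-interior voxel —
  grid-phase aliasing and axial partial volume push it below threshold over
  most of the arc → masked at 4 mm;
* a 2-mm voxel (body diagonal 3.5 mm) always fits wholly inside the 9-mm tube
  → the catheter never vanishes at 2 mm.

The sinogram-domain variant (`method = "sinogram_acf"`, threshold 1.005 on the
attenuation correction factor) is implemented and selectable; in a 2.5-D model
it cannot reproduce the straight/curved distinction, because the long
LOR-along-catheter paths that make straight catheters visible to a clinical
3-D mask are oblique rays the model excludes.

The supra-threshold object shadow is dilated by one radial bin
(`mask_dilate_bins`) before the tail is taken as its complement, so projector
interpolation cannot leak object counts into the tail.

**Scatter scaling is per slice**, for both TF-SSS and MC-SSS, matching the
per-plane character of the published sinogram profiles and confining the
artifact axially exactly as observed: an inflated scale in one slice does not
spill into its neighbours. Fitted scales are clipped at zero. For MC-SSS the
scatter fraction comes from the data-generation transport by default
(`sf_source = "truth"`); a reconstruction-side rerun on the μ-map and the
uncorrected image (`sf_source = "mumap_estimate"`) is available — the
distinction is immaterial here but documents what a vendor implementation
would do.

**Reconstruction.** Pixel-basis OSEM, 3 iterations × 11 subsets (132 angles /
11 = 12 views per subset) — a deliberate simplification of the clinical
blob-based, time-of-flight, 33-subset list-mode algorithm, whose machinery is
immaterial to the mechanism; relaxation is omitted. The scatter estimate
enters the forward model additively by default; the literal
subtract-and-clip variant (`scatter_mode = "presubtract"`) is provided and
produces the same zero-driving behaviour.

**What the generator does not emulate.** Randoms, detector normalization,
dead time, time-of-flight, positron range, photon non-collinearity,
out-of-plane scatter (beyond the acceptance factor), sphere/lung inserts, and
CT physics (attenuation truth is assigned directly; the printed catheter
attenuation of 1.03 cm⁻¹ is read as 0.103 cm⁻¹, a decimal-point slip, since
511-keV attenuation of plastics is ≈ 0.1 cm⁻¹). Passing tests therefore show
that the *mechanism* — mask failure → scale inflation → non-negativity
clipping → halo — is faithfully reproduced, not that absolute clinical SUVs
would be.

## Problem sizes and numerics

Default desk geometry: 144 radial bins × 132 angles, 60 slices of 4 mm,
576-mm field of view; 2 × 10⁶ Monte-Carlo decays allocated across slices in
proportion to activity; the single-scatter estimate is computed on every
second slice (66 directions, 20-mm scatter grid) and interpolated axially. A
full four-method experiment takes about 2–3 minutes on one CPU. Noiseless
trues are the default (Poisson resampling is available) so that every reported
number is reproducible from the configuration and master seed alone;
`derive_seed()` expands that seed per stage. Degenerate inputs — all-air
μ-maps, zero-count slices, unfittable tails — return zeros with warnings or
explicit errors rather than propagating NaN.

## Worked example

```{r example}
library(halosim)
rep <- run_experiment(run_config(pattern = "tube_curve", seed = 1))
suv_summary(rep, 6:55)        # per-slice SUV over catheter-spanning slices
rep$halos$TFS4                # halo regions under the coarse tail fit
subset(rep$scale_table, TFS4 > 1.2 * MCS4)  # slices with inflated scales
```

Per-slice curves (the per-slice SUV table has one row per slice and method)
and radial profiles (`sinogram_profiles()`) reproduce the study's two
signature plots: SUV collapsing only where and only for the methods whose
mask fails, and the scaled scatter estimate exceeding the measured emission
around the mismatch.
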