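# halosim

Simulation of the photopenic **halo artifact** that indwelling urinary
catheters cause in FDG PET/CT through inaccurate scatter correction — and of
the corrections that avoid it.

## The problem

A urinary catheter drains intensely radioactive urine (here 150 kBq/mL
against 3.0 kBq/mL ≡ SUV 1.0 in the body) along the *outside* of the patient.
Clinical scatter correction, tail-fitted single-scatter simulation (TF-SSS),
scales an analytic single-scatter estimate `ŝ` so that `k·ŝ` matches the
measured emission `m` in the **tail** — sinogram bins that, according to the
attenuation map (μ-map), contain scatter only:

```
k = argmin Σ_tail ( m − k·ŝ )²  =  Σ m·ŝ / Σ ŝ²   (per slice, clipped at 0)
```

When activity is present in bins the μ-map believes are empty — urine that
shifted after the CT, or a curved catheter erased from a 4-mm μ-map by the
partial-volume effect — those unscattered counts inflate `k`. The scaled
scatter then exceeds the prompts around the catheter, and the multiplicative
OSEM update (non-negative by construction) drives the surrounding body to
zero: a halo that can hide real tumours. The Monte-Carlo-scaled correction
(MC-SSS) instead sets, per slice,

```
k = SF · Σ m / Σ ŝ ,     SF = scattered / (true + scattered)
```

with `SF` from a Monte-Carlo transport — no tail, no mask, no mismatch
sensitivity.

`halosim` reproduces the whole chain at desk scale: phantom generation with
controlled μ-map/activity mismatch, attenuated parallel-beam projection,
in-plane Monte-Carlo photon transport (Klein–Nishina scattering, energy
window 460–665 keV), analytic single-scatter simulation, tail-fitted and
MC-scaled scaling, OSEM reconstruction calibrated to SUV, per-slice SUV
curves, and the two-step halo-detection rule (near-zero runs in the corrected
image that are positive without scatter correction).

## Worked example

```r
library(halosim)

rep <- run_experiment(run_config(pattern = "tube_curve", seed = 1))
suv_summary(rep, 6:55)   # catheter-spanning slices
#>   method  mean    sd  n
#>     MCS4 0.990 0.014 52
#>      NSC 1.337 0.015 52
#>     TFS2 0.974 0.030 52
#>     TFS4 0.875 0.227 52

rep$halos$TFS4[, c("size", "slice_min", "slice_max", "nsc_mean")]
#>   size slice_min slice_max nsc_mean
#> 1 1679         5        56     1.28   (and 3 smaller regions)
nrow(rep$halos$TFS2)   #> 0
nrow(rep$halos$MCS4)   #> 0
```

Read: with the catheter coiled into an arc, the 4-mm tail-fitted correction
(TFS4) produces halo regions and per-slice SUV collapses (down to 0.07 at the
most oblique slices), while the 2-mm tail fit and the MC-scaled correction
stay at SUV 1.00 ± 0.05 and detect no halo — NSC reads high (≈ 1.34) because
scatter is left in the data. For `pattern = "urine_shift"`, the halo appears
under *both* tail fits exactly at the CT−/PET+ segment (mean SUV ≈ 0.41
there) and never under MC scaling; for `pattern = "skin_attached"` no method
shows an artifact.

A thin CLI over the same functions lives at `inst/cli/halosim.R`
(`generate` and `experiment` subcommands, YAML configs via `load_config()`).

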