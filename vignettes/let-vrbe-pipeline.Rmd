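---
title: "LET mixing, variable RBE and plan-comparison metrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LET mixing, variable RBE and plan-comparison metrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonRBE)
```

## What the pipeline computes

Proton plans are optimised and reported assuming a constant RBE of 1.1, yet
the biological effectiveness of protons rises with dose-averaged LET, which
increases sharply where protons stop. When a beam's distal edge sits against
a cardiac structure, a fixed-RBE dose report can understate the biologically
weighted dose there by several Gy(RBE). This package quantifies that effect
for a plan: it combines per-beam LET grids, thresholds them to adequately
dosed voxels, applies the McNamara variable-RBE model, and extracts the
comparison metrics used in clinical plan evaluation.

The chain for each plan is:

1. per-beam physical dose `d_b` and dose-averaged LET `L_b` grids
   (simulated here, or imported);
2. composite LET by relative-dose weighting,
   `L = sum(d_b L_b) / sum(d_b)`, undefined (sentinel `NA`) where no beam
   deposits dose;
3. exclusion of voxels below 5% of the maximum composite dose (within the
   body contour when available) — LET estimated from very few particles is
   noise, and such voxels are clinically irrelevant;
4. RBE-weighted dose `D_RBE = D × RBE(d, L)` per voxel, with
   `d = D / n_fractions`;
5. metrics per structure and per RBE setting, plus voxel-wise difference
   maps `Δdose = D_vRBE − D_1.1`.

Thresholding happens *after* combination, anchored to the composite-plan
maximum: combination order follows the processing chain the analysis
mirrors, and a per-beam anchor would couple the exclusion region to beam
weighting in a way the composite metrics should not see.

## The RBE model

With `RBEmax = c1 + c2·LET/(α/β)` and `RBEmin = c3 − c4·√(α/β)·LET`,

```
RBE(d, LET) = [ sqrt((α/β)² + 4d(α/β)RBEmax + 4d²RBEmin²) − (α/β) ] / (2d)
```

* Coefficients default to the published McNamara fit
  (0.99064, 0.35605, 1.1012, 0.0038703) and are overridable in
  `rbe_params()` / the study config.
* `α/β` defaults to 2 Gy (late-responding OARs); the default study also runs
  3 and 10 Gy as a sensitivity analysis. One `α/β` applies per run —
  per-structure values would be a config extension, and the comparison
  tables already report every structure under each run's setting.
* `RBEmin` is floored at 0: beyond the model's fitted LET range a negative
  value would feed a negative term into the square root; clamping is the
  defensible extrapolation.
* The quotient is evaluated in the rationalised form
  `(2(α/β)RBEmax + 2d·RBEmin²) / ((α/β) + sqrt(·))`, which is algebraically
  identical but avoids catastrophic cancellation as `d → 0`; the degenerate
  identity (forcing `RBEmax = RBEmin = c` gives `RBE ≡ c`) then holds to
  rounding error for any `d` and `α/β`.
* `d = 0` is a domain error by design: zero-dose voxels are excluded
  upstream rather than evaluated at a singular limit.
* Dose per fraction is the voxel's total dose divided by the fraction
  count — uniform fractionation, the standard assumption when a plan is
  delivered unchanged across fractions.

Excluded voxels (sentinel LET, zero dose) carry the value 0 in RBE-weighted
grids and are flagged; they never enter LET or vRBE statistics but keep
their physical dose for dose-only metrics.

## The synthetic phantom and beam model

The simulator stands in for patient CT plus Monte-Carlo transport. It is
*not* a dose engine: it produces fields with the right structure — flat
target dose, distal falloff, a distal LET spike positioned against a
cardiac structure — so that the analysis layer can be exercised and tested
end to end.

**Geometry.** A uniform water body (axial ellipse, 290 × 190 mm), a 52-cc
CTV in the anterior mediastinum, a heart posterior-inferior to it with a
left-atrium-like substructure abutting the CTV's posterior (distal) surface,
two lungs lateral to the beam corridor, spinal cord, esophagus, and a
deliberately sub-0.1-cc coronary-like structure (`lmca`) that exercises the
"structure too small" reporting path. All geometry lives in the config file,
not in code. Depth along a beam is geometric path length from body entry —
exact for uniform water, and HU calibration is out of scope.

**Depth dose.** A pseudo-Bortfeld pristine curve: a power-law plateau
`∝ 1/(R − z)^0.23`, a boxcar boost over the final `peak_width_mm`, and
Gaussian smoothing with `straggling_sigma_mm` producing the peak and distal
falloff. Two calibration passes pin the entrance-to-peak ratio at
`plateau_dose` (default 0.35). This reproduces the features the analysis
depends on (flat-summable plateau, peak near `R`, Gaussian distal edge)
with every parameter testable; a full analytical Bragg model would add
physics the downstream metrics never see.

**Depth LET.** `L(z) = let_plateau + let_scale·(1/(R−z+s) − 1/(R+s))`,
clipped at `let_cap` and held at the cap through the distal falloff. The
entrance anchoring makes `L(0) = let_plateau` exactly. Defaults: plateau
1.5 keV/μm, scale 25 keV/μm·mm, softening 2 mm, cap 15 keV/μm — plateau LET
of 1–3 keV/μm and distal-edge values in the 6–15 keV/μm band, the range
reported for clinical proton fields.

**SOBP weights.** Nonnegative least squares (`pracma::lsqnonneg`) on a
0.5-mm depth grid solves layer weights for unit dose across the CTV's depth
interval; layers span that interval plus 6 mm on both sides at 3-mm spacing,
which keeps the achieved ripple ≤ 0.3% (tolerance 3%, warning beyond).
Layer LETs are combined with the same relative-dose weighting used across
beams, so generation and analysis share one mixing definition.

**Lateral profile.** A box aperture (projected CTV + 10 mm margin)
convolved with a 4-mm-σ Gaussian penumbra, hard-zeroed beyond 3σ. With
these defaults the nominal plans meet the 98%/95% coverage criterion with
D98 ≈ 99% of prescription — tight but realistic for a robustly planned
target.

**Normalisation.** Per-beam grids are rescaled by one global factor so the
CTV *median* composite physical dose equals the prescription
(19.8 Gy / 11 fractions). TPS normalisation conventions vary and none is
universal; the median is stable against penumbra tails and is flagged in
the config as a convention, not physics.

**Determinism.** Generation is deterministic given the config; optional
multiplicative dose noise (`noise$dose_sd_frac`, default 0) is the only
stochastic element and draws from the seeded session RNG, so a fixed seed
reproduces grids bit-identically.

## What the defaults emulate — and what they do not

The default study (four arrangements: 0°; 10°/350°; 30°/330°;
10°/350°/180°) realises the geometry of concern: anterior beams stop
against the heart, so their high-LET shell sits in cardiac tissue, and the
posterior field in the three-field plan waters the mixed LET down. Passing
tests on this phantom demonstrate that the *analysis* is correct and that
the *directional* clinical findings (fewer fields → higher OAR near-max
LET; vRBE > fixed-1.1 near distal edges; α/β spread concentrated at high
dose) emerge from the mechanism, not that any patient's numbers are
reproduced. Real plans differ in heterogeneity, scattering, nuclear halo,
optimizer trade-offs and contour anatomy; absolute Δdose magnitudes here
(≈6–10 Gy(RBE) near-max in the abutting atrium) exceed typical patient
values (≈2–5 Gy(RBE)) precisely because the synthetic geometry pushes the
full-dose distal edge directly into the structure.

## Numerical conventions

* **D0.1cc** sorts structure voxels descending (stable radix sort for
  tie-breaks) and interpolates linearly in cumulative volume between the
  bracketing voxels; a voxel-quantized variant sits behind
  `interpolate = FALSE`. A structure smaller than the requested hot volume
  raises a classed `"structure_too_small"` condition — reported as missing,
  never extrapolated.
* **DVHs** are cumulative with `volume(0) = 100%`, non-increasing by
  construction; V5/V10 read from a DVH agree with `v_dose()` to one bin.
* **Volumes** are exactly voxel count × voxel volume; no partial-volume
  modelling at 2 mm.
* **Coverage** D98 reuses the D0.1cc machinery with the hot volume set to
  98% of the structure volume.
* **Grid files** store doubles with 17 significant digits (exact IEEE
  round trip); the DICOM RT Dose codec scales to 31-bit integers
  (quantization ≤ 3 × 10⁻¹⁰ relative) and is an interchange convenience,
  with the text format remaining the format of record.
* Problem sizes: the default phantom is 150 × 100 × 50 voxels at 2 mm
  (750k voxels, matching the 2-mm Monte-Carlo grids such analyses use);
  unit tests run a 60 × 50 × 20 / 4-mm configuration, chosen so the full
  suite exercises every path at interactive speed.

## Known limitations

No Monte-Carlo transport, heterogeneities, or nuclear secondaries; no
treatment-plan optimization (apertures emulate SFO geometrically); no
track-averaged LET; no DICOM RT Struct/Plan handling; one α/β per run. The
simulator's LET cap makes extreme distal-edge LET saturate at 15 keV/μm,
which slightly compresses near-maximum LET contrasts between plans whose
distal edges both reach the cap.
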