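---
title: "Models and methods behind ventrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ventrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ventrecon` studies how much the anatomical content of an EIT reconstruction
model matters when thoracic EIT is used to profile regional lung ventilation.
This vignette documents the models, the numerical choices and the design
decisions, so that every result the package produces can be traced to an
explicit assumption.

## Coordinate and image conventions

All geometry lives in a 2D cross-section at the electrode-belt plane,
in millimetres: `x` grows towards the animal's left, `y` from anterior
(ventral) to posterior (dorsal). Images are 32×32 matrices whose row index
follows `y` (row 1 = anterior) and whose column index follows `x`
(column 1 = the animal's right); anteroposterior profiles are therefore
row-band sums. The image bounding box is the tight axis-aligned bounding box
of the thorax contour, so pixels are in general rectangular. Electrode 1
sits at the anterior midline and numbering proceeds clockwise viewed from
cranial (towards the animal's left first); both conventions are
configurable, and only pin down an image rotation that would otherwise be
arbitrary.

## Forward model

The forward problem uses the complete electrode model (CEM) on extruded
2.5D meshes:

* The 2D section is triangulated from a boundary-conforming point set:
  boundary nodes are placed exactly at the electrode patch edges (so every
  electrode is covered by whole faces), lung and heart contours are seeded
  as interior node rings, and the interior is filled with a hexagonal
  lattice at the density implied by the requested element count. A Delaunay
  triangulation of this point set follows the organ boundaries through the
  seeded rings rather than through constrained edges; element region labels
  (background / lung / heart) are assigned from the mid-plane centroid of
  each element, which is also the property the tests verify. Mesh
  generation is deterministic for identical inputs.
* The section is extruded symmetrically about the electrode plane into five
  tetrahedralized prism layers, with z-levels graded so that the mid-plane
  band exactly matches the electrode patch height (default 0.1 × extrusion
  height; extrusion height defaults to one effective thorax radius). Prisms
  are split into tetrahedra with the index-sorted diagonal rule, which keeps
  faces conforming across neighbours.
* Linear (P1) tetrahedral elements; per-electrode contact impedance
  (default 10⁴ Ω·mm² = 100 Ω·cm²); grounding by constraining the electrode
  potentials to zero sum through a Lagrange multiplier. Conductivity is
  relative (background 1) and the solver is real-valued — the excitation
  frequency is metadata only, appropriate for difference imaging.
* The stimulation scheme is skip-4: drive `k` injects ±3 mA between
  electrodes `k` and `k+5` (mod 32); measurements use the same pairs.
  Channels sharing an electrode with the drive are carried as invalid slots
  (`NA`) rather than dropped, so frames keep the hardware-style 1024-channel
  layout with 928 valid channels.
* Sensitivities are computed by the adjoint method,
  `J[c,e] = −∫ₑ ∇u_drive · ∇u_meas dV`, with the measurement field driven by
  unit current. Because conductivity is constant along the extrusion in the
  2.5D setting, the inverse parameter space is the set of 2D triangles; tet
  columns of `J` are summed per parent triangle.

Verification: reciprocity holds to 1e-8 relative; scaling the full
admittance (σ and the contact admittance) scales voltages exactly;
central finite differences reproduce Jacobian columns to better than
1e-3 relative at step 1e-3 (one-sided differences at very small steps are
dominated by solver round-off, which is why the tests use the central
form); voltages agree within 2% under 4× mesh refinement.

## Inverse models

**GREIT.** Training targets are small conductive discs (contrast −1,
mimicking inflation, so ventilation is positive in the tidal images) of
radius `ts`×R placed at every pixel center inside the body. Their voltage
signatures are `J·x`, where `x` holds the fraction of each element covered
by the disc — approximated smoothly by the lens overlap of the target disc
with the element's equal-area disc, which keeps signatures well defined
when `ts`×R is below the element size, as it is for the recommended
`ts = 0.06` on desk-scale meshes. Desired images are hard discs of radius
`rw`×R (no taper), clipped to the body mask. The reconstruction matrix is
the regularized regression `R = X Yᵀ (Y Yᵀ + λΣₙ)⁻¹` with identity channel
noise covariance by default.

**Gauss-Newton.** One-step solution map `(JᵀJ + λ²P)⁻¹Jᵀ` in the 2D element
space with `P = I` (Tikhonov), `P = diag(JᵀJ)` (NOSER) or `P = L᷀L` for the
element-adjacency graph Laplacian `L` (Laplace; a 1e-8 relative diagonal
shift makes it invertible against its constant null space). The map is
assembled through the prior Cholesky factor and the dual channel-space
normal equations, so its cost is governed by the 928 channels rather than
the element count, and composed with the element-to-pixel interpolation
(area-weighted averaging via subsampled point location). The sign is
flipped so that a lung conductivity decrease appears positive, matching the
GREIT convention.

**Noise figure.** The EIT literature invokes the noise figure under varying
conventions; `ventrecon` uses the amplification-ratio form
`nf = [mean|Rn|/mean|n|] / [mean|Ry_c|/mean|y_c|]` in expectation over
i.i.d. unit-variance Gaussian channel noise, evaluated in closed form
(`E|Rn|ᵢ = √(2/π)‖Rᵢ‖`, the same factor appearing in `E|n|`), with image
means over in-body pixels and `y_c` the signature of a small central
target. Absolute noise-figure values depend on this convention; this
matters when comparing settings across implementations.

**Calibration.** `calibrate_nf()` matches the regularization weight to a
requested noise figure. The noise figure decreases with λ over the
operating branch but has a shallow non-monotone tail under extreme
regularization (the λ→∞ limit is the scale-invariant back-projection map,
whose noise figure is a floor of ≈0.13–0.15 for these models). The
calibrator therefore scans a 25-point log-λ grid, selects the
smallest-λ crossing of the target — the least-regularized matching
solution — and bisects inside that sub-interval to 1% relative. Both
trainers expose closed-form noise-figure evaluations through a shared
eigendecomposition, so recalibration across λ costs almost nothing.

## Tidal-image pipeline

Voltage referencing is time difference (`v − v(t_r)`) or normalized time
difference (`v/v(t_r) − 1`); the reference frame is the first detected
end-expiration frame (a provisional first-frame reference is used to detect
phases, then the series is re-referenced — end-expiration is the
conventional EIT baseline). Breath phases are local extrema of the mean
in-body pixel signal after a 0.5 s moving average, with a minimum extremum
separation of 0.6 × the nominal breath period; each end-inspiration is
paired with the nearest following end-expiration and incomplete trailing
breaths are dropped. The tidal image is the mean of the per-breath
differences.

Post-processing follows two documented paths: the 10%-of-maximum threshold
is applied when no anatomical mask is used (profiles `vd1`, `vd2`, `vd3`);
the anatomical lung mask replaces the threshold for `vd2p` and `vd3p`.
For `vd2p` the subject's lung contours are carried into the averaged-model
frame by the centroid/area similarity transform that aligns the two thorax
contours. The reference profile is computed from the ground-truth aeration
image restricted to the lung mask, mirroring the radiologist lung
delineation used with registration-based reference data — the synthetic
truth has no registration error, but keeping the restriction preserves the
procedure being emulated.

## Statistics

Profiles are compared by RMSE over the 32 bands (percentage points).
Pooled Pearson correlation and Bland-Altman statistics are computed over
(subject, band) pairs after the agreement filter (at least one of the two
values positive); both the filtered and unfiltered correlations are
available, the filtered one being primary. Because band differences are not
normally distributed, Bland-Altman agreement is summarized by the median
bias and the 2.5th/97.5th percentiles with linear interpolation between
order statistics (quantile type 6 — the convention under which a worked
5-point example spans its extreme differences). Variant comparisons use the
Kruskal-Wallis test with tie correction, followed by all-pairs
Tukey-Kramer comparisons on rank sums (the Nemenyi procedure, studentized
range with infinite degrees of freedom): a parametric Tukey test on raw
errors would contradict the nonparametric omnibus choice. Settings sweeps
rank settings within each subject by 2D image correlation (average ranks on
ties, failures ranked last) and order settings by mean rank, which is
invariant to monotone transformations of the correlation scores.

## Synthetic data generator

The generator stands in for synchronized animal CT/EIT validation
recordings; its defaults are the study conditions the package targets:

* Breathing at 6 min⁻¹ sampled at 48 Hz for 30 s (1440 frames, three
  breaths), skip-4 belts of 32 electrodes, 3 mA.
* The averaged phantom is a fixed low-order Fourier thorax (effective
  radius ≈110 mm) with two elliptical lungs and a heart; it is a package
  asset, not a published population shape library. Individual phantoms
  deform it with a seeded smooth radial field (modes 2–5, unit variance,
  amplitude 0.04 of the local radius), applied to thorax and organs
  together so containment is preserved; this yields thorax shape mismatches
  ΔS of roughly 3–8% against the averaged contour, the scale the mismatch
  metric is meant to resolve.
* Lung conductivity is modulated as
  `σ(t) = 0.2·(1 − a(y)·δσ·g(t))`, `g(t) = (1 − cos 2πft)/2`, with peak
  swing `δσ = 0.2` (small enough for approximate linearity of difference
  imaging) and a linear anteroposterior weighting `a(y)` of slope 0.3
  (posterior-favoring, volume-weighted mean 1). The gradient value is a
  plausibility choice for healthy supine animals; no quantitative value is
  established, and it is exposed as a parameter.
* Because time enters only through the scalar amplitude `g(t) ∈ [0,1]`,
  the forward problem is solved exactly at nine amplitude knots and channel
  voltages are interpolated with natural splines over `g` for all frames;
  the elliptic solution is smooth in `g`, and the interpolation error is
  orders below the additive noise. White Gaussian channel noise is added at
  50 dB SNR relative to the RMS breathing-induced voltage swing — the
  scale of a well-functioning belt on a quiet recording.
* Simulation meshes are refined 2× relative to the reconstruction meshes
  and use a shifted interior lattice, so the two discretizations share no
  interior nodes (inverse-crime guard; asserted in the tests).
* The ground truth is the 128×128 per-pixel conductivity swing between
  end-expiration and end-inspiration, supported on the lung mask — the
  aeration-change analog produced directly rather than through simulated
  CT plus image registration, whose errors are exactly what anatomical
  masking mitigates in real data. Cardiac activity is not simulated; the
  breath-averaged pipeline would suppress it, and a configuration hook
  exists but defaults off.

What passing tests on this generator do *not* show: robustness to electrode
movement or contact changes, cardiac and perfusion signals, reactive
(complex-valued) tissue behavior, registration errors in the reference
modality, or 3D breathing mechanics. The generator's purpose is controlled,
reproducible contrast between reconstruction geometries, not physiological
realism.

## Problem sizes and defaults

Reconstruction models default to ~20k tetrahedra (≈1300 2D triangles ×
15), which resolves the 32×32 image well; 200k-element models are a
configuration choice, not a different code path. The cohort evaluation
uses 8 subjects at those sizes; the settings sweep uses 3 subjects at ~6k
elements with noise figures {0.15, 0.3, 0.5} × {TD, NTD} × {uniform,
weighted} for both algorithms (Laplace prior for Gauss-Newton), a reduced
but structurally faithful version of a full settings scan. GREIT's
recommended operating point (nf 0.15, ts 0.06, rw 0.15, weighted
background, TD) is the package default. `ts = 0.06` lies below the
conventional scan range (0.1–0.9); the implementation deliberately permits
it.

## Known limitations

* The organ boundaries are node-seeded rather than edge-constrained in the
  triangulation; elements straddling an organ boundary take the label of
  their centroid. At the default densities this affects a ~one-element-wide
  band.
* The polygon-clipping ΔS is exact up to the coordinate quantization of the
  clipping library (~1e-6 relative); a rasterization fallback cross-checks
  it.
* Electrode patches are rectangular bands on the lateral surface; curved
  electrode models and contact-impedance estimation are out of scope.
* The noise-figure floor (back-projection limit) means very small noise
  figures may be unreachable for some geometry/settings combinations; the
  calibrator reports the achievable range when a target is outside it.
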