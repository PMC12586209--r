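---
title: "Methods: DXA-based femoral strength and hip-fracture risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DXA-based femoral strength and hip-fracture risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femfall)
```

## What the package models

Hip-fracture risk in older adults is usually screened with the DXA-derived
T-score, but a substantial fraction of hip fractures occur above the
densitometric osteoporosis threshold. Two complementary biomarkers improve
stratification: the FRAX 10-year hip-fracture probability (FRAX-HFP, a
clinical risk calculator) and femoral strength, the peak force the proximal
femur can carry in a sideways fall, estimated from image-based finite
element models. A third quantity, the trochanteric soft tissue thickness
(TSTT), modulates the force actually delivered to the bone when a person
falls on the greater trochanter.

`femfall` implements, end to end and fully synthetically, the analysis
chain such a study runs:

1. a **calibrated cohort generator** for a multi-ethnic (Chinese, Indian,
   Malay) population of community-dwelling adults aged 60 and above, with
   per-sex, per-ethnicity marginal means/SDs, linear age trends and
   cross-correlations;
2. a **parametric proximal-femur density phantom** (head sphere + neck
   cylinder + shaft cylinder, cortical shell over trabecular core) with an
   areal-BMD projection linking the 3D phantom to the 2D quantity DXA
   reports;
3. a **density-to-modulus material mapping** with partial-volume
   correction;
4. a **tetrahedral finite-element solver** that poses the femur in the
   sideways-fall configuration and reports femoral strength as the peak
   head reaction force;
5. the **standing-TSTT prediction equation** (sex- and ethnicity-specific
   linear map of the supine measurement) plus a simplified supine
   measurement on planar phantom images;
6. **cohort statistics** (pooled means, one-way ANOVA, ANCOVA-adjusted
   means, LOWESS age trajectories with bootstrap bands) and
   **threshold-based risk cross-classification**.

No clinical data ship with the package; every input is generated in code.

## The synthetic cohort

Within each sex-by-ethnicity cell, the vector (age, weight, height, supine
TSTT, FRAX-HFP, total-hip aBMD, femoral strength) is drawn from a
multivariate normal with the cell's published marginal means and SDs
(`table1_cohort_params()`; 980 males, 1224 females in six cells). By
default the draw is truncated by rejection to physical bounds (age >= 60,
non-negative measurements, FRAX-HFP <= 100%); `truncate = FALSE` gives the
raw normal draw, whose sample moments are unbiased for the cell
parameters — the calibration tests use that mode because truncation at
zero visibly shifts the mean of strongly right-spread variables such as
Chinese-female FRAX-HFP (mean 5.64%, SD 5.03%).

The source table publishes only marginals, so the joint structure is a
documented modelling choice, not an estimate:

* aBMD–strength +0.7 (both reflect bone quantity), aBMD–FRAX −0.5 (aBMD
  enters the FRAX model protectively), TSTT–weight +0.6 (adiposity);
  all other non-age pairs 0.
* Age enters through correlations implied by linear trend slopes,
  `r(age, v) = slope_v * sd_age / sd_v` (clipped to ±0.9), so each
  conditional mean is linear in age with the requested slope while the
  marginals stay calibrated. Default slopes per year: weight −0.2 kg,
  height −0.15 cm, supine TSTT −0.02 cm, FRAX-HFP +0.1 %, aBMD −0.004
  g/cm², strength −0.05 kN — signs follow the expected age trajectories
  (declining bone and soft-tissue measures, rising fracture probability),
  magnitudes chosen once as plausible for this age range and exposed in
  `default_age_slopes()`. All six per-cell correlation matrices are
  verified positive definite at construction.

Three columns are derived, never drawn: BMI = weight/(height/100)²
(exactly, by invariant); the T-score as a per-sex linear map of aBMD whose
reference mean/SD are backed out of the pooled aBMD and T-score marginals
(`tscore_reference()`), so T-score and aBMD can never disagree in sign of
deviation; and standing TSTT from supine TSTT via the prediction equation.
The tabulated TSTT is interpreted as the *supine* measurement: for Indian
females the tabulated mean (4.21 cm) lies below that cell's standing
intercept (12.26 cm), so it cannot be the standing output.

BMI is derived, so the published tstt–BMI association is imposed through
weight instead; with the BMI identity this induces the intended
association without breaking the invariant.

What the generator does *not* emulate: non-normal tails, cohort selection
effects, scanner noise, missingness, or any real joint dependence beyond
the documented correlations. Passing tests therefore demonstrate that the
pipeline recovers *its own generating assumptions*, not that those
assumptions describe any real population.

## The standing-TSTT equation

`standing_tstt()` applies `TSTT = slope * TSTT_SUP + intercept` with
sex- and ethnicity-specific coefficients shipped as an editable table
(slopes 0.51–0.63; intercepts 2.29–12.26 cm). Unknown (sex, ethnicity)
pairs are an error — there is no pooled fallback. Inputs above 10 cm warn:
the linear fit is only trusted over the calibrated range, and whether the
intercept-dominated Indian/Malay fits extrapolate meaningfully is an open
question we flag rather than answer. The supine measurement on planar
images (`measure_tstt_sup()`) is a deliberately simple two-threshold edge
walk at the widest bone row of a search band; it is a stand-in validated
only on constructed phantoms, not a clinical image pipeline.

## Phantom, material mapping, and the FE solver

**Phantom.** `generate_femur_phantom()` voxelizes the three-primitive
union at `voxel_spacing` (default 2 mm): voxels within
`cortical_thickness` (default 3 mm) of the outer surface get the cortical
density (default 1.2 g/cm³), deeper voxels the trabecular density (0.3
g/cm³). `project_abmd()` integrates density along a grid axis and averages
over the projected footprint — exactly linear in density and
translation-invariant — and `target_abmd` rescales the phantom to a
requested areal BMD.

**Material chain.** `density_to_modulus()` applies, in order: mineral to
ash density (`0.877 ρ + 0.0789`), ash to apparent density (÷ 0.6), and the
power law `E = 6850 ρ_app^1.49` MPa. These constants are literature-style
defaults, prominently overridable in `calibration_params()`; none is a
measured property of a specific scanner. Negative intermediates clamp to
zero before the power law. Yield stresses are strain-based (yield strain
0.01, compression/tension ratio 1.2) and the nominal 1 m/s loading rate
survives only as the static `rate_factor` multiplier (default 1) — the
solver is quasi-static and has no rate state. Elements sampling outside
the volume bounds are void (density and modulus 0): the ash intercept must
not give space beyond the scan a modulus.

**Partial-volume correction.** Surface voxels straddling the bone boundary
read artificially low. `correct_partial_volume()` replaces values within
`depth` 6-connected layers of the mask boundary by the nearest interior
value, propagated layer by layer. Interior voxels are never touched and
replaced values are existing interior values, so the interior min–max
range is preserved. A mask with no interior after peeling is an error.

**Meshing.** `mesh_density_volume()` lays a uniform lattice at
`target_edge` over the volume and splits accepted cells into six
tetrahedra along a consistent main diagonal (conforming by construction).
Cell acceptance samples the center and eight corners and keeps cells with
a majority (≥ 5/9) in bone. This choice matters: center-only acceptance
erodes a half-cell rim of the *stiffest* (cortical) material and made
coarse and refined meshes differ structurally rather than numerically,
while any-sample acceptance overshoots symmetrically; the majority rule is
approximately volume-unbiased and is what lets the refinement check pass
as a genuine discretization test. Linear 4-node tetrahedra at 3 mm are the
default trade-off for test-suite-scale problems; 10-node quadratic
elements (midside nodes shared per edge, four-point Gauss integration) are
available via `order = 2` and are strictly no stiffer on the same
geometry.

**Posing and boundary conditions.** `pose_femur()` applies a pure rigid
rotation: shaft axis to +x, neck into the x–z plane pointing up, then the
internal rotation (default 0°) about the shaft and the adduction (default
−5°) about the horizontal axis; the head drive direction is global −z.
Supports are idealized nodal constraint sets, not contact surfaces: the
head patch (ball of `patch_radius`, default 8 mm, anchored at the centroid
of the topmost node layer of the head — a centroid anchor is stable under
rigid-motion round-off where an arg-max node is not) is driven downward;
the trochanter patch is fixed along the load axis only (frictionless); the
distal nodes nearest the horizontal line through the distal shaft-end
centroid are constrained transversely, permitting rotation only about that
axis — the hinge. The phantom has no condyles, so the distal shaft-end
centroid stands in for the condyle center: a documented geometric
deviation. The exact support patch sizes are not published; the
patch-radius default is an implementation choice.

**Solve.** Displacement control in `n_increments` (default 20) steps with
secant-stiffness iteration per increment: each element follows a bilinear
law in an equivalent-strain measure (von Mises stress at unit modulus),
yielding when von Mises stress exceeds the tension or compression yield
stress — selected by the sign of the volumetric strain — with post-yield
tangent `tangent_fraction * E` (default 5%). Non-converged increments are
bisected up to 5 times, then flagged and the run continues. Femoral
strength is the peak resultant head reaction, in kN. Zero-modulus elements
are stabilized at 10⁻⁹ of the peak modulus so rim voids cannot orphan
nodes; the perturbation is orders of magnitude below every reported
tolerance.

The solver is verified against closed forms rather than against clinical
values, which are unreachable without the real cohort: the constant-strain
patch test (exact), the linear oracle in the elastic limit (0.1%), the
rigid-plastic column plateau `A·σ_y` (5%), global equilibrium (10⁻⁶ of
peak), power-law density scaling of elastic strength (10%, with a
zero-intercept calibration — the ash intercept deliberately breaks pure
scaling otherwise), frame indifference under rigid pre-rotation (1%), and
mesh-refinement stability (< 10%). These are run on coarse phantoms
(voxel 2–3 mm, edges 4–8 mm), sized so the whole battery completes in a
few minutes on one CPU; the vignette and tests state these sizes as the
package's own problem-size choices.

## Cohort statistics

`pooled_mean()`/`pooled_sd()` recompose pooled descriptives from subgroup
cells — the internal-consistency check applied to the published table.
`anova_oneway()` is the classical between/within F with (k−1, N−k)
degrees of freedom; zero within-variance with unequal means returns
F = ∞, p = 0 by convention. `age_adjust()` fits the classical single-slope
ANCOVA `value ~ age + group` and evaluates adjusted group means at the
grand-mean age; the group test is the extra-sum-of-squares F conditional
on age. The adjusted-means formulation (rather than residualization) was
an open choice; it is the standard epidemiological reading of "adjusted
for age". Slope-by-group interaction is deliberately out of the default
model. A constant age vector falls back to plain ANOVA with a warning.

`lowess_trajectory()` wraps Cleveland's LOWESS (span 2/3, one robustness
iteration by default — the method is named in the source analysis, its
span is not), evaluates on an even age grid, and builds percentile
bootstrap bands (199 resamples, seeded) because the published 95% bands do
not state their construction. Local linear smoothing reproduces noiseless
linear data exactly at full span, which is the main correctness oracle.

## Risk classification

`classify_subjects()` applies: osteoporotic if T ≤ −2.5, osteopenic if
−2.5 < T < −1, normal if T ≥ −1; FRAX-at-risk if FRAX-HFP ≥ 2%; fragile
if strength < 3 kN (females) / 3.5 kN (males). The boundary conventions
(inclusive T and FRAX thresholds, strict strength inequality) are package
choices — the source text never states inclusivity. The strength
thresholds carry a provenance caveat: they derive from a Korean cohort
and are not validated against incident fractures. `cross_tabulate()`
reports both the exclusive four-way partition (both / frax-only /
strength-only / neither) and the marginal totals per biomarker, because
published summaries mix the two views; both are emitted explicitly to
avoid that ambiguity.

One qualitative caveat discovered during validation: with the published
marginals under a normal model, Chinese and Malay females have nearly
identical probabilities of falling below the 3 kN threshold (≈ 31.6% vs
32.9%), so on synthetic cohorts "Chinese flagged most by every method"
holds for FRAX-HFP and T-score in both sexes and for strength in males,
but the Chinese/Malay female strength ranking is inside sampling noise by
construction. The tests assert the strongest ordering the generating
parameters support.

## Reproducibility and numerical choices

* Every stochastic entry point takes an explicit seed; generators save and
  restore the global RNG state. The pipeline derives per-stage seeds from
  the master seed by a fixed counter (cohort +1, phantom +2,
  trajectories +3) so stages reproduce in isolation.
* Secant iteration tolerance 10⁻⁶ (relative, on element moduli), at most
  40 iterations per increment; elastic increments converge in one pass.
* Trilinear interpolation is used for all volume sampling; it is exact for
  linear fields, which the element-mapping test exploits.
* Geometry is mm, density g/cm³, modulus MPa (so forces come out in N),
  TSTT cm, strength kN; converters sit at module boundaries only.
* Outputs carry an 8-hex-digit FNV-1a hash of the configuration so files
  from different runs cannot be mixed silently.

## Known limitations

The largest deviation from a production pipeline is the solver itself:
quasi-static, small-strain, with idealized nodal supports instead of
explicit dynamic contact at 1 m/s; inertia, soft-tissue padding in the FE
model, fracture-surface prediction and damage-history material state are
all out of scope. The phantom is a three-primitive idealization with no
2D→3D statistical shape registration. FRAX-HFP is consumed or simulated,
never computed from its 12 clinical risk factors. The cohort has no
incident fractures, so no threshold can be validated against outcomes
here — classification quality statements are structural (partition and
marginal consistency, monotonicity), not clinical.
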