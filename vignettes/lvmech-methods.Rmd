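---
title: "Methods: synthetic ventricles, surface strain, hemodynamic forces and flow metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ventricles, surface strain, hemodynamic forces and flow metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmech)
```

# Scope and data model

`lvmech` quantifies left-ventricular mechanics from one data object: a
cardiac cycle of a closed triangulated endocardial surface with fixed
connectivity, where each vertex is a material point. All coordinates are in
mm, volumes in mL, times in seconds; conversions happen only at I/O and at
the force normalization. The analysis assumes the sequence covers exactly
one heartbeat, frame 0 at time 0 and the last frame strictly before the
period `T`, and that the surface is watertight (every edge shared by two
consistently oriented triangles) — enclosed volumes are then exact
divergence-theorem sums over facets.

# The synthetic ventricle generator

No public dataset of tracked endocardial surfaces accompanies the kind of
exercise-echocardiography study this package targets, so the generator is a
first-class module, not a test fixture: it defines the conditions under
which every downstream stage is validated.

**Geometry.** The end-diastolic chamber is a half prolate spheroid (apex at
−L, basal plane at z = 0, length-to-radius ratio 2 by default, a typical
LV aspect), closed by a triangle fan around the annulus centroid. A 60°
sector of the cap offset toward +x is marked as the aortic orifice — about
3 cm² at a 90 mL chamber, a physiologic aortic area — and the rest of the
cap acts as the mitral orifice. The reference mesh is rescaled once so its
*discrete* enclosed volume equals the requested EDV exactly; since every
frame is an affine image of the reference, frame volumes then track the
target waveform exactly (up to torsion-induced facet distortion, which is
below 0.1% at the default 10° twist).

**Volume waveform.** Systole is a half-cosine from EDV to ESV over the
systolic fraction of the cycle; diastolic dV/dt is the sum of two
raised-cosine bumps (E and A waves) whose amplitudes solve the filled-volume
constraint at the prescribed E:A peak ratio, separated by a diastasis.
Wave widths are fixed fractions of the diastolic duration (0.42 and 0.34),
so the diastasis shrinks in absolute terms as heart rate rises and
disappears into the `"merged"` single-wave mode used for recovery-like
phases. The default systolic duration follows a square-root rate
correction, 0.3·√T seconds clamped to 25–60% of the cycle: ~34% at rest,
~51% at a peak-exercise heart rate of 174 bpm.

**Deformation.** Two modes:

* `"split"` (default): volumetric shortening s(t) = V(t)/EDV is partitioned
  into a longitudinal scaling s^p and a circumferential scaling
  s^((1−p)/2), p = `long_circ_split`, plus a torsion whose apex-base angle
  grows with contraction. The hoop stretch is exactly s^((1−p)/2), which the
  strain pipeline must recover; p = 0.25 puts more shortening in the
  circumferential direction, reproducing the clinical ordering
  |GCS| > |GLS|. A `split_lead` makes the dominant contraction lead in early
  systole (the split exponent ramps from p − lead to p over the first half
  of systole), which transiently stretches the cross direction and produces
  the early positive secondary-strain peak seen in measured GSS curves.
* `"isotropic"`: each frame is a uniform scaling s^(1/3) of the reference.
  This is the one axisymmetric closed-surface map whose in-plane stretches
  are spatially uniform, so it serves as an exact strain ground truth: a
  target end-systolic dominant stretch λ is imposed by choosing
  ESV = λ³·EDV, and with a frame landing exactly on end systole
  (systolic fraction 0.5 with an even frame count) GPS = λ − 1 to
  round-off.

**Cohort sampling.** Per-phase heart rate, EDV and ESV are drawn from
normal distributions truncated at ±3 SD and at physiologic bounds
(HR ∈ [30, 250] bpm, EDV > ESV); infeasible joint draws are redrawn up to a
bounded retry count. The default phase table uses the published cohort
means ± SD for the five exercise phases and the control group, the per-phase
E/A ratios (1.6, 6.3, 1.5, 1.1, 1.2) — illustrative values, not population
parameters — and the typical frames per cycle at each phase (26 at rest
down to 11 at peak), since temporal resolution genuinely degrades as wall
velocity rises.

**What the generator does not emulate:** regional wall-motion heterogeneity,
measurement noise and tracking drift, mitral leaflet geometry, through-plane
twist gradients beyond the linear law, or inter-subject shape variation
(every subject shares the parameterized template, which is also what makes
cohort averaging correspondence trivial). Passing tests therefore
demonstrate correctness of the *operators* under controlled kinematics, not
robustness to clinical segmentation artifacts.

# Volume curve and E/A detection

The sampled volume is interpolated with a periodic cubic spline onto a
2048-point uniform grid and differentiated there by centred differences, so
peak detection does not depend on the (possibly coarse) frame timing. E and
A are the two largest positive local maxima of dV/dt after end systole,
ordered in time; maxima below 5% of the tallest diastolic peak are treated
as numerical ripple (`min_peak_frac`), and a single surviving wave is
flagged `merged` with the A peak and E/A reported as `NA` rather than 0.
E/A is measured on dV/dt peaks (mL/s), not on orifice velocities. The
E-wave window runs from the zero-crossing before the E peak to the E–A
local minimum (or the post-E zero-crossing when merged). Sequences under 10
frames per cycle — the accepted reliability floor for wall-motion analysis —
are analyzed but flagged.

# Registration and averaging

The rigid registration is computed at end diastole and applied to all
frames: the area-weighted surface centroid (robust to nonuniform
triangulation) moves to the origin, the annulus-center→apex axis aligns
with −z, and the roll about z puts the aortic center in the +x half-plane.
Volume is exactly invariant. Cohort averaging is vertex-wise on phase
fraction t/T (heart rate differs across phases, so wall-clock time is not a
valid common clock) after periodic cubic-spline resampling to a common
frame count; whether averaging should interpolate before or after vertex
means is not observable from summary data, and resample-then-average is the
adopted convention.

# Surface Lagrangian strain

Per triangle, reference and current edge vectors are expressed in
orthonormal tangent frames; the in-plane deformation gradient is
F = E_cur·E_ref⁻¹, and the rotation is removed by polar decomposition,
U = (FᵀF)^(1/2) via the closed-form symmetric 2×2 eigendecomposition. The
strain is S = U − I with eigenvalues λ_p ≤ λ_s (reported in percent). The
first tangent basis vector is the projection of the global longitudinal
axis onto the triangle plane — so the longitudinal and circumferential
normal strains are simply S₁₁ and S₂₂ — with the longest edge as fallback
when the axis is nearly normal to the triangle (the basal cap). For equal
eigenvalues the principal direction is reported along the longitudinal
basis vector (any choice is valid; this one is reproducible).

Global values (GPS, GSS, GLS, GCS) are reference-area-weighted means of
per-triangle scalars, not eigenvalues of a mean tensor: spatial averaging
of invariant scalars is basis-independent and matches how global strain is
reported clinically. Weighting by reference rather than current area is a
convention (the alternative rescales systolic values by a few percent
relative); it is fixed and documented here. The basal cap is excluded from
global averages by default — it is a virtual closure, not myocardium.
Degenerate triangles propagate as masked elements and must stay below 1% of
reference area. End-systolic strain values are taken at the frame of
minimum volume.

# Hemodynamic forces

The force exchanged between blood and chamber is evaluated from boundary
data alone as

F(t) = ρ [ d/dt ∮ x (v·n) dS + ∮ v (v·n) dS ],

the momentum-budget form of the force integral for a closed moving surface.
The printed form of this integrand circulates with ambiguous grouping; the
grouping above is fixed empirically by the rigid-body oracle, which has a
unique consistent answer: for a rigid translation of a closed surface the
convective term vanishes and ∮x(a·n)dS = aV, so F = ρVa exactly, and a
sinusoidal translation with peak acceleration g must give a dimensionless
amplitude of exactly 100%. Wall velocities are spectral derivatives of the
vertex trajectories (the Nyquist mode is dropped; centred differences are
available for comparison, and an optional Fourier truncation at a configurable
harmonic count smooths low-frame-count phases). On the orifice patches the
no-slip wall velocity is replaced by a binary-valve plug: outward
|dV/dt|/A_AV through the aortic patch during ejection, inward through the
mitral patch during filling. Facet quadrature uses centroid values, which
is exact for the linear first integrand, giving the closed-surface identity
to 1e−6 relative at any resolution. The first integral is differentiated in
time spectrally across frames. Forces are reported dimensionless,
f = F/(ρ g V(t)) × 100 — independent of ρ by construction — with
ρ = 1060 kg/m³ and g = 9.81 m/s² as configurable defaults.

The six longitudinal parameters follow the standard definitions: RMS
amplitudes over the cycle, systole and diastole (LVLF, LVsysLF, LVdiaLF),
and lobe impulses: LVsysIm averages the contiguous positive lobe within
systole; LVs averages (in magnitude) the negative interval starting at the
first zero-crossing after that lobe, which may extend into early diastole —
the window is ended at the force zero-crossing, not at the E peak, because
the force sign is the observable that defines suction; LVdiaIm averages the
positive lobe immediately after. Lobes are located on the linearly
interpolated series with zero-crossing endpoints; an absent lobe is
reported `NA`, never 0. On the synthetic ventricle the dimensionless force
magnitudes come out several-fold larger than typical clinical percent
values: the plug closure concentrates all inflow momentum on the flat basal
cap and the boundary estimate omits the intraventricular pressure-gradient
redistribution a full flow solve would provide. Comparisons across phases
of the synthetic cohort are meaningful; absolute percent levels are not
calibrated to clinical values, and the package makes no claim that they
are.

# Vorticity and vortex formation time

Vorticity is evaluated on gridded velocity fields (any solver or imaging
export; the package itself does not solve the flow): centred second-order
curl at interior mask nodes, one-sided at the mask boundary, full-grid
fallback on single-node chords. The dimensionless mean is
ω̄ = (T/V)∫|∇×v| dV by mask-restricted midpoint quadrature. Two analytic
fixtures close the loop: solid-body rotation (|∇×v| = 2Ω exactly, so
ω̄ = 2ΩT to round-off) and Hill's spherical vortex, whose interior vorticity
grows linearly with cylindrical radius and whose volume-mean modulus is
(45π/32)·U/a in closed form. The diastolic vorticity peak is taken as the
maximum over frames after end systole.

The vortex formation time integrates v_MV/d over the E-wave window, with
v_MV = Q_MV/A_eff and the effective diameter d = √(4A_eff/π) (the diameter
of a circle of area A_eff — the only dimensionally consistent reading of
the usual shorthand). Q_MV comes from dV/dt during filling by mass
conservation with the binary valve. Classification uses the published
bands: optimal 3–4 inclusive, acceptable up to 5, high above. The default
effective mitral area is 400 mm² (a mid-range pediatric value); VFT scales
as A_eff^(−3/2) at fixed flow, so this constant matters for absolute values
and is exposed in the configuration.

# Statistics

Welch's unequal-variance t-test implements the unpaired comparison (the
pooled-variance variant is a special case that is never safer); two
degenerate zero-variance groups return the limit values p = 1 or 0 rather
than erroring inside a cohort loop. Normality screening reports moment
skewness and excess kurtosis with default flags |skew| ≤ 2 and
|kurtosis| ≤ 4 — conventional screening cut-offs, exposed as arguments.
Regressions are ordinary least squares with R² and the slope's two-sided
p-value; a constant response is reported as R² = 0 with a flag. No
multiple-testing correction is applied: the design has one planned contrast
per metric. Stroke volume is derived per subject (EDV − ESV) before
summarizing.

# Pipeline, problem sizes and determinism

`run_simulate` / `run_analyze` / `run_report` orchestrate the cohort study:
datasets are written as per-frame ASCII PLY plus a JSON sidecar (period,
times, landmarks, orifice markers, spec) and a manifest; analysis
quarantines failing subjects and continues; reports carry the manifest
checksum. The default study — 19 subjects × 5 phases at 40×20 mesh
resolution (1600 triangles) with phase-typical frame counts — runs end to
end in a few minutes on one core; this size gives volume discretization
error well under 1% and strain/force oracle errors near round-off, and the
test suite exercises the same settings. All randomness flows from one seed
through R's RNG, so reruns are bit-for-bit identical.

# Known limitations

* The generator's deformation is globally axisymmetric; regional strain
  heterogeneity and tracking noise are not modeled, so detection robustness
  on clinical data is untested here.
* Dimensionless force magnitudes are not calibrated to clinical levels (see
  above); only their structure and relative changes are validated.
* E/A detection at very low frame counts (≤ 12) inherits spline distortion
  of narrow filling waves; the generator's ground-truth waveform is the
  reference for accuracy claims, and mesh-sampled detection at peak-exercise
  frame rates is expectedly biased.
* Vorticity requires an externally supplied velocity field; no
  intraventricular flow is solved.
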