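---
title: "stemshield: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stemshield: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

After total hip arthroplasty the femoral stem carries part of the load that
previously stressed the proximal femur. Where the bone is unloaded it
resorbs (stress shielding, typically the calcar, Gruen zone 7); where load
concentrates it appositions (often distally, zones 3/5, or as cortical
hypertrophy under a malpositioned stem). Short stems are designed to load
the metaphysis more physiologically, and the clinical question is whether a
simple patient-specific biomechanical model — built from a single early
post-operative frontal radiograph — can predict the per-zone remodeling
seen two years later, and how sensitive each stem design is to varus/valgus
malposition.

`stemshield` implements that analysis end to end as a tested pipeline. No
patient images are available to this package, so the radiograph-derived
geometry is replaced by a parametric generator, and a synthetic-cohort
module provides closed-loop validation: labels are produced by a known
ground-truth mechanostat, the pipeline must recover its parameters.

# Model chain

## Geometry

A right proximal femur in the frontal plane (+x lateral, +y proximal, mm):
a periosteal contour (outer cortex) and a strictly interior endosteal
contour bound the cortical shell; the interior is cancellous. The femoral
neck is resected; the head centre remains as a landmark above the resection
plane. The outline is built from ~14 interpretable length parameters plus
the CCD angle (see `femur_params()`), smoothed by chord-length cubic
splines. Construction is homogeneous of degree 1 in the length parameters,
so scaling all lengths scales areas exactly quadratically — a property the
test suite asserts.

Three stem archetypes follow the classes of short-stem designs they stand
for: a short lateral-engaging stem with a pronounced shoulder flare
(`PROXIMA`), a curved neck-sparing stem (`COLLO_MIS`), and a longer
triple-tapered stem (`MINIMA`). Each is a tapered polygon around a
quadratic-Bezier centreline.

Placement rotates the stem about the neck-resection centre
(positive angle = varus, tip swings laterally), then advances it into the
bone along the neck axis until it fits. Two deliberate choices:

* **Seating anchor.** A malaligned stem is seated *at least as deep* as the
  minimal feasible neutral seating. Without this anchor the tilted contour
  seats shallower, and the lateral drift of the insertion direction cancels
  the tilt — malposition would then spuriously *reduce* cortical load,
  contradicting the mechanism the position sweep is meant to expose
  (a tilted stem driving its contour towards the cortex).
* **Containment.** The placed stem must stay inside the periosteal contour
  (with a 0.8 mm margin) but may cross the endosteal boundary into the
  cortical wall: that cortical contact *is* the malposition mechanism of
  interest, and the mesher resolves the crossing exactly.

## Gruen zones

The "modified" zone demarcation of the radiographic scheme is not published
in a reproducible form, so a documented stand-in is used: the stem axis
line separates lateral (zones 1–3, proximal→distal thirds of the stem
length) from medial (zones 7–6–5), and zone 4 is the band of bone within
one local stem width distal to the tip. Bone slightly proximal to the
shoulder centre (up to 0.15 stem lengths) joins the proximal zones, so the
calcar cut and trochanter base are covered. The zone map is a point
classifier, so disjointness and coverage hold by construction; the mirror
symmetry (zone 1 ↔ 7, 2 ↔ 6, 3 ↔ 5 under reflection) is asserted in tests.

## Meshing

A conforming constrained Delaunay triangulation is built in-package (no
suitable library exists in the target environment): densified contour
points plus a jittered hexagonal interior lattice are triangulated by an
incremental Bowyer–Watson kernel (C++); constraint edges not present are
recovered by recursive midpoint insertion; crossing constraint contours
(tilted stem vs endosteal boundary) are mutually split at their
intersection points first. Region tags (cortical / cancellous / implant)
are assigned by centroid with implant priority; a centroid within 1e-9 mm
of a boundary is nudged towards the triangle's incenter before the test, so
tagging is deterministic.

Exactly collinear boundary points make the incircle predicate degenerate,
so the kernel triangulates *deterministically hash-perturbed* copies of the
points (amplitude 5e-8 of the element size) while all downstream geometry
uses the exact coordinates — a cheap form of symbolic perturbation. Mesh
area equals the polygon area to machine precision and tagged region areas
equal their polygon areas; both are asserted in tests.

## Materials

Homogeneous linear-elastic classes (the source literature for bone
properties is cited, not printed, in the study this package emulates;
values are standard and fully overridable):
cortical E = 17,000 MPa, cancellous E = 1,000 MPa, titanium-alloy implant
E = 110,000 MPa; Poisson 0.3 throughout; densities 1800 / 600 / 4500
kg/m^3. A density–modulus law applied per element is deliberately out of
scope; classes are homogeneous.

## Loading

Single-leg-stance loads, forces in N with g = 9.81:

* **Joint contact force**: magnitude 2.38 × body weight × g (peak walking
  load), tilted by the patient's Pauwels angle from vertical towards
  medial, applied at the head-centre landmark.
* **Abductor reaction** at the greater trochanter. The study text gives no
  magnitude, so two documented conventions are provided.
  `"equilibrium"` (default) closes the frontal force balance
  F_A = −(F_joint + W_partial) with W_partial = (5/6) BW·g, the
  stance-phase partial body weight; `"fixed"` uses the classic ratio
  |F_A| = 1.6 BW·g at 21° from vertical. Whether the 2.38 BW resultant
  already contains the abductor contribution is not resolvable from the
  source text; the equilibrium mode documents our interpretation, and the
  closure identity is asserted to 1e-9 N.
* **Fixation**: both displacement components of every node on the distal
  cut (y = 0).

Because the head centre lies above the resected, meshed domain, the joint
load is transferred onto the implant shoulder node set by a minimal-norm
distribution that reproduces the total force *and* its moment about the
node set (a rigid-neck transfer, like an RBE3 element). Plain 3-node
barycentric attachment — used for the abductor force, whose location is a
mesh vertex — would extrapolate enormous equilibrating nodal forces for a
point 30 mm outside the mesh and create singular stress artefacts.

## Plane-stress FE solve

Three-node constant-strain triangles, plane stress; sparse symmetric
assembly; direct sparse factorization plus one step of iterative
refinement (relative residual ≤ 1e-9 asserted on every solve). Element
strain energy density U = ½ σ:ε in MPa (1 MPa = 1e6 J/m^3). Verified
against a uniform-traction patch test (exact to 1e-8), a Timoshenko
cantilever (2 %), the work–energy identity Σ U·A·t = ½ fᵀu (1e-8), rigid
modes in the unconstrained null space, and exact mirror equivariance.

**Thickness**: the single absolute-calibration knob. Stresses scale with
1/t and SED with 1/t². The default t = 35 mm matches the 2D diaphyseal
cortical section (two ≈6 mm walls × t) to a literature-typical 3D cortical
cross-sectional area of ≈400 mm², so 2D stresses — and hence the stimulus
that the 2/12 J/kg setpoints presuppose — sit at the physiological scale.
(A 10 mm slab, a common generic choice, over-stresses the section
threefold and pushes nearly every zone above the apposition setpoint.)

## Stimulus and mechanostat

The remodeling stimulus is mass-specific strain energy:
S = U × 1e6 / ρ in J/kg. Following the source convention of dividing
interface SED by *cancellous* bone density, the default (`"literal"`) mode
uses ρ = 600 kg/m^3 for every bone element; `"regional"` mode uses each
element's own class density.

Classification uses the Frost mechanostat with a lazy zone:
S > T_high → apposition; S < T_low → resorption; otherwise no activity.
The thresholds themselves belong to the lazy zone ("exceeds" / "falls
below" are strict), defaults (T_low, T_high) = (2, 12) J/kg.

Per-zone aggregation takes the **area-weighted median** of element stimuli
over the bone–implant interface band (bone elements with centroid within
3 mm of the stem contour): the smallest value whose cumulative area
strictly exceeds half the zone's band area. The strict rule is chosen so
that with equal weights and odd counts it reduces to the ordinary sample
median; a plain element median is available but is mesh-density dependent.

## Calibration

* **Lower threshold**: first quartile of the stimuli in zones with observed
  resorption, by sorted-order linear interpolation at position
  1 + 0.25(n−1) (the most common quantile convention, stated explicitly);
  at least 4 values are required, otherwise the configured default is used.
* **Upper threshold**: exhaustive grid search ("brute force") over
  [3, 25] J/kg in 0.25 steps; every grid point is scored by 3-class
  accuracy against the observed labels (apposition-vs-rest is available as
  a switch; the source does not say which objective was used). The
  calibrated value is the midpoint of the contiguous accuracy-maximizing
  plateau containing the first maximizer — a documented, deterministic
  tie-break for an objective that is piecewise constant.

## Malposition sweep and cortical overload

`position_sweep()` runs 3 stems × {varus +5°, neutral, valgus −5°} on one
patient geometry with identical mesh settings and reports, per cell, the
maximum cortical stimulus and the cortical overload fraction (area share
of cortical band elements with S > T_high). The ±5° default is
configurable; it lies within clinically reported malposition.

## Statistics

Mann–Whitney U with an exact regime (full enumeration when both samples
are ≤ 8 and tie-free) and a documented normal approximation with tie and
continuity corrections otherwise; Pearson chi-square of independence
without continuity correction, flagging expected counts < 5. Pairwise
class comparisons are reported unadjusted, mirroring the zone-level
box-plot comparison; zones are pooled across patients (the within-patient
correlation this ignores is a known simplification). Significance 0.05 is
reported, never enforced.

# The synthetic cohort: what it does and does not emulate

`generate_cohort()` reproduces the *statistical skeleton* of the study
population: 15 patients balanced 5/5/5 over the three stems; body weight ~
Normal(70, 12) kg truncated to [45, 110] (cohort median 70 kg); Pauwels
angle ~ Normal(16, 3)° clipped to [5, 30]; CCD ~ Normal(130, 3)° clipped
to [121, 139]. Geometry variability is a global similarity scale
(0.92–1.08) times independent shape jitter (0.92–1.08) on parameters that
cannot violate the landmark invariants — fully independent ±10% jitter can
put the head centre below the trochanter apex, i.e. produce non-anatomical
geometry. Observed labels come from the forward mechanostat applied to the
pipeline's own zone medians, optionally corrupted by a class-uniform flip
with probability `noise_rate` (the simplest model of radiographic reading
error). All generators are pure functions of their seeds and leave the
global RNG untouched. In the rare case that a drawn geometry cannot seat
its stem, the cohort runner redraws that patient deterministically from a
derived seed — the in-silico analogue of a surgical exclusion.

Not emulated: radiographic image formation and digitization error,
selection for "clear radiographic evidence of remodeling" (a label
selection bias, off by default), anatomical correlations beyond the
similarity model, 3D effects (anteversion, out-of-plane bending). A green
closed-loop test therefore establishes that the pipeline is *internally
consistent and invertible* — labels generated by the stated mechanostat at
(2, 12) J/kg are recovered by the brute-force calibration with accuracy
1.0 and a plateau midpoint within ±1 J/kg — not that the model is
clinically validated.

# Numerical choices and degenerate inputs

* Meshing determinism: interior lattice jitter uses a fixed internal seed;
  meshing twice gives identical meshes.
* Constraint recovery and area refinement are capped (12 and 6 rounds);
  both converge in 1–3 rounds on all exercised geometries.
* Placement scans seating depth in 0.5 mm steps; failure to seat raises a
  `placement_failure` error rather than returning a partial result.
* Zone aggregation raises `empty_zone` if a zone has no band elements
  (cannot happen for the shipped geometries; guards misuse).
* Calibration with no resorption-labelled zones falls back to the
  configured default lower threshold and records the fallback.
* A cohort config without an explicit seed is an error, never a silent
  default.

# Known limitations

2D frontal-plane model with bonded interfaces: no press-fit prestress, no
friction or micromotion, no anteversion. Homogeneous material classes.
One load case (peak walking). The Gruen-zone demarcation is a documented
stand-in for the unpublished modified scheme. Absolute stimulus values
inherit the thickness calibration; conclusions should rest on
within-model comparisons (zones, alignments, designs), which is how the
pipeline uses them.
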