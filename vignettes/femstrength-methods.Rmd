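---
title: "CT-to-fracture-load modelling with femstrength: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-to-fracture-load modelling with femstrength: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femstrength)
```

## The problem

Quantitative-CT finite element analysis (QCT-FEA) predicts how much
compressive load a proximal femur carries before it fractures, from a
clinical CT scan alone. The chain is: calibrate the scanner's Hounsfield
units (HU) against a hydroxyapatite phantom scanned with the specimen; build
a specimen-specific tetrahedral model; map each element's CT attenuation to
an equivalent mineral density and from there to elastic and yield
properties; then push the model through a displacement-controlled nonlinear
solve in the stance configuration and read fracture load and stiffness off
the predicted force--displacement curve, exactly as one would from a
materials-testing machine.

femstrength implements that chain end to end, together with the validation
statistics used to compare FE predictions against cadaver compression tests
(paired regressions, laterality rank tests, age trends) and a
synthetic-specimen generator that stands in for cadaver data, which is not
publicly available for studies of this kind.

## Calibration

The phantom carries rods of known mineral density (0, 100 and 200 mg/cm^3
in the reference design). `rod_mean_hu()` averages HU over voxels whose
centres fall inside each rod region --- regions are supplied explicitly
(world-space cylinders or masks), never auto-detected, so the step is
deterministic and testable. `fit_calibration()` is an ordinary
least-squares line `density = slope * HU + intercept`; `hu_to_density()`
applies it and converts to g/cm^3. A voxel belongs to a region iff its
centre is inside; no partial-volume weighting is attempted because no
defensible weights exist without knowing the scanner's point-spread
function. Negative fitted slopes are flagged rather than silently
accepted. The density carried forward is hydroxyapatite-equivalent density
treated directly as the rho of the property laws; whether those laws expect
ash, apparent or HA-equivalent density is genuinely ambiguous in the
source literature, so the choice is a single documented convention rather
than a hidden transformation.

## Geometry

`segment_bone()` thresholds the volume, keeps the largest 6-connected
component, and returns the triangulated boundary of the voxel mask. This
is a blocky iso-surface: vertices sit on voxel corners, so the surface
deviates from the true interface by at most half a voxel diagonal (0.3 mm
at the default scanner spacing), which is far below the 1.5 mm element
size downstream.

`cut_and_orient()` applies the specimen cut: a plane 120 mm distal of the
greater-trochanter-tip landmark along the shaft axis, tilted 20 degrees in
the coronal plane, with the cut cross-section closed by a centroid fan
(exact for the star-shaped sections every supported geometry produces).
The model is then moved to a canonical frame --- cut face on z = 0 with
its normal along -z, anterior axis along +y --- so that the applied load
is the global vertical and the shaft makes the stance angle with it.
Landmarks and axes are explicit inputs (the generator provides them for
phantoms); anatomical landmark detection is out of scope. The rigid map
back to the CT frame travels with the geometry so material sampling always
happens in scanner coordinates.

`tetrahedralize()` fills the surface at a 1.5 mm global edge length by
default. No tetrahedral mesher exists in this R environment, so the
package carries its own: a lattice snapped to the bounding box is split
into six tetrahedra per cell (Kuhn subdivision, face-conforming across
cells), and cells crossing the boundary are clipped against the zero level
set of the surface's signed distance by marching tetrahedra. The lattice
pitch is `target_edge/sqrt(2)`, which puts the median tet edge on the
target. Consequences worth knowing:

* box-like surfaces whose bounding box coincides with the surface are
  meshed exactly (the cube volume test is exact to machine precision);
* curved boundaries are linearly interpolated, so enclosed volume
  converges at second order in the pitch (the radius-10 mm sphere meshes
  to within 2% at a 1.5 mm edge);
* the clipped skin can contain pairs of faces whose internal diagonals
  disagree (hanging nodes on the one-element boundary layer). This is a
  variational crime confined to the skin; the patch test on snapped
  domains is exact and the bar stiffness benchmarks converge, which is
  the accuracy class a constant-strain-tet pipeline occupies anyway.
* near-degenerate slivers produced by the clip are dropped (relative
  volume below 1e-10), and all tets are re-oriented to positive volume.

`overlay_shell()` attaches 0.2 mm membrane triangles to every boundary
face except the cut face and faces buried in the resin-fixed band,
mirroring the cortical shell overlay of the modelling protocol.
`tag_boundary_sets()` marks the resin box (all nodes within 30 mm of the
cut plane by default) and the loaded spherical cap (boundary nodes within
a cone about the vertical through the femoral-head centre; the centre is
fitted by an algebraic sphere fit to the top boundary band unless given).

## Material mapping

Each tet's HU is the mean over voxels whose centres it contains,
with trilinear interpolation at the centroid as the fallback for tets
smaller than a voxel. The normative density--property laws are the
vertebral power laws adopted after the source study's pilot comparison:

* modulus: `E = 1890 rho^1.92` MPa for `rho > 0`, `E = 0.001` MPa at and
  below zero density (the printed condition on the power-law branch is a
  typo --- a power law is undefined for negative density and the
  companion line covers zero --- and is read as `rho > 0`);
* yield: `sigma_c = 284 rho^2.27` MPa for `rho > 0.2`, and a literal
  `1e20` MPa sentinel below, so marrow-like elements never yield;
* the final modulus is clamped to [0.01 MPa, 20 GPa]. The clamp wins over
  the raw 0.001 MPa zero-density value during assignment, but
  `keller_modulus()` still returns the raw value so both printed
  statements remain representable;
* Poisson ratio 0.3 everywhere; tensile yield is 0.8 times compressive;
  shell elements run through the same chain with their HU fixed at 1000.

Other literature laws (femoral power laws) can be registered through
`material_law()` with caller-supplied coefficients; only the vertebral law
ships with numbers because only its coefficients are published in full in
the adopted protocol.

Yield uses the pressure-sensitive Drucker--Prager surface
`f = alpha I1 + sqrt(J2) - k`. `dp_params()` calibrates `alpha` and `k`
so the surface passes through uniaxial compression at `sigma_c` and
uniaxial tension at `0.8 sigma_c`:
`alpha = (1-r)/(sqrt(3)(1+r))`, `k = r sigma_c (alpha + 1/sqrt(3))`;
`r = 1` degenerates to von Mises. The `1e20` sentinel never overflows
because the yield check works on stresses, not on powers of `k`.

## Nonlinear solve

The solver is displacement-controlled and quasi-static: the cap node set
advances along the vertical in fixed increments (0.1 mm by default; the
physical 5 mm/min rate is represented as rate-independence), the resin
band is fully fixed, and each step runs Newton iteration on the
out-of-balance force until the free-dof residual falls below `newton_tol`
(1e-6) relative to the reaction norm. Design choices:

* elements are linear (constant-strain) tetrahedra with one integration
  point --- exact for this element --- assembled through a global sparse
  strain--displacement operator so tangent reassembly is a block-diagonal
  product, not an element loop;
* post-yield behaviour is elastic--perfectly-plastic with associated
  flow: the closed-form radial return scales the trial deviator and
  shifts the pressure, with apex projection for tension states beyond the
  cone tip. This is the principal modelling assumption the source
  protocol leaves open (it names only the yield criterion);
* the tangent is the continuum elastoplastic tangent; after 10
  iterations, or if its factorisation fails (a fully plastic plateau has
  a singular tangent), the solver falls back to the elastic stiffness;
* each step starts from an elastic-predictor lift of the incremented
  constraints --- without it the first iteration sees spurious yielding
  near the driven face and Newton can cycle;
* the "uniform load on the resin cap" is realised as an equal prescribed
  vertical displacement of the cap node set with free transverse motion
  (a rigid-cap analog), because the cap's geometry and stiffness are not
  specified; the resin box and cap are boundary conditions, never meshed
  solids, which removes unprovided resin constants from the model;
* shells contribute membrane stiffness only and stay elastic. At 0.2 mm
  thickness on 1.5 mm triangles their bending energy is negligible, and
  their plastic work is second-order next to the solid elements carrying
  the same stress.

The solve reports the force--displacement curve (driven-node reaction per
step), a cumulative yielded-element fraction, per-step convergence
diagnostics including the fixed/driven reaction balance, and the final
stress field.

## Fracture metrics

`fracture_load_fea()` implements the prediction rule: the reference
stiffness is the least-squares slope of the initial linear segment
(grown while each forward tangent stays within 5% of the running fit,
minimum three samples), and fracture is the force at the first segment
whose tangent has dropped more than 20% below that reference, with the
drop required to persist one further segment (or be the last) so a single
noisy segment cannot fire it.

`fracture_load_mechanical()` operationalises "the slope rapidly
decreased", which the experimental protocol never quantifies. It applies
the same 20% rule to a moving-average-smoothed signal, but with two
robustness changes that matter on measured data: the reference slope is
fitted over the samples between 20% and 80% of the provisional peak force
(pooling dozens of samples; the three-point initial-segment rule has tens
of percent of noise at realistic sampling rates), and the reported load is
refined as the intersection of pre-drop and post-drop least-squares lines.
On a noise-free bilinear recording the intersection is the knee load
exactly, so the mechanical and FE detectors agree exactly there; under
load-cell noise the refinement averages over many samples instead of
quantising the answer to the nearest sample, which is what makes a
within-3% reproducibility figure achievable at 1% force noise. A
sample-quantised detector cannot do better than roughly
`sqrt(2) sigma/(1 - p)` of force scatter (noise sigma, post-knee slope
fraction p) no matter how the smoothing window or sampling rate is
chosen, which is 4--5% under those conditions.

`stiffness_20_80()` is the protocol's stiffness: the least-squares slope
over samples between 20% and 80% of the fracture load. Where the
"maximum fracture load" anchoring this window is ambiguous (detected load
vs global maximum), the detected fracture load is used; the two coincide
for monotone curves.

`linreg()`, `mann_whitney_u()` (exact enumeration for groups of at most
8 without ties, tie-corrected normal approximation otherwise) and
`cohort_report()` provide the five validation analyses: mech-vs-FE
regressions for load and stiffness, load-vs-stiffness per source,
right-vs-left rank tests, and load-vs-age regressions, plus a multiple
regression of load on age, sex and side.

## The synthetic-specimen generator

Cadaver CT volumes and test recordings are not deposited with studies of
this kind, so the generator supplies every input the pipeline needs with
known ground truth.

**Phantoms** (`make_phantom()`) voxelise a parametric specimen --- bar,
cylinder, or a femur-like union of a shaft, a 20-degree neck and a
spherical head --- with a cortical rim and a trabecular interior, plus the
three calibration rods, at the scanner's acquisition spacing (0.3, 0.3,
0.5 mm) by default. Partial volume is emulated by supersampled averaging
(8 sub-samples per axis by default) and imaging noise as additive Gaussian
HU. The rod *sampling regions* returned to the calibration step are
eroded by one voxel footprint so every sampled voxel is pure rod; without
the erosion the rod means are diluted by the partial-volume skin and the
fitted slope is biased by several percent. The femur-like shape is a
union of primitives, sufficient to exercise the cut, the cap tagging and
stance loading; it is not an anatomical atlas, so passing tests say
nothing about shape-specific stress concentrations in real femora, about
scanner physics beyond additive noise, or about real trabecular
heterogeneity.

**Curves** (`make_curve()`) are bilinear with a programmed knee (always
sampled exactly) and seeded Gaussian force noise.

**Cohorts** (`make_cohort()`) draw paired left/right femora from
`n/2` cadavers. Latent strength follows
`load = 15856 - 142.6 * age + eps` (the reported fitted age line is the
default, as configuration rather than truth), ages uniform on 74--101
years; the FE measurement is biased by the reported between-method line
(`fea = 0.8201 * latent + 1702.6`, the direction of that fit consistent
with the reported group means --- an OLS line must pass through them);
stiffness is `load/2.7 + eta` with the 2.7 mm divisor taken from the
reported mean load over mean stiffness. Noise scales (latent 1000 N,
instruments 700 N, stiffness 150 N/mm) were derived once, jointly, from
the three reported R-squared values (age 0.49, load 0.62, stiffness
0.55) at the design size n = 20, and are not revisited. Every generator
output is bit-reproducible under a fixed seed.

## Numerical choices and degenerate inputs

* Lattice pitch `target_edge/sqrt(2)`; sliver cutoff 1e-10 relative
  volume; signed-distance parity rays carry a deterministic 1e-4-pitch
  jitter so symmetric geometry cannot graze triangle edges.
* The constrained linear solve uses sparse Cholesky and verifies the
  factorisation against a deterministic probe right-hand side, because a
  singular (floating) system can otherwise return a plausible-looking
  particular solution; insufficient constraints are an error, not a
  warning.
* Degenerate inputs error early with the offending entity named: empty
  rod regions, empty segmentations (with the HU range printed), cut
  planes that miss the surface, zero-area shells, degenerate tets,
  empty boundary node sets, all-equal rod HU.
* `cap_angle_deg` of zero is treated as the degenerate empty cap.
* Tie-break in the fracture detectors: detection indexes the first
  persistent below-threshold segment; the reported index for the refined
  mechanical load is the sample nearest the line intersection.

## Problem sizes used in the shipped tests

The test-suite exercises the same code paths the full protocol uses but at
sizes a laptop handles comfortably: bars of 10 x 10 x 40--100 mm at 2--5 mm
edges (about 5,000--40,000 tets), a radius-10 mm sphere for volume
convergence, femur-like phantoms at 1 mm voxels and 3.5--4 mm edges, and
cohorts of 20 specimens with 50--100 seeded replicates for the statistical
calibration checks. These sizes were chosen so each property is measured
well inside its tolerance; nothing in the implementation is specific to
them, and the defaults (0.3/0.3/0.5 mm voxels, 1.5 mm edges) reproduce the
protocol scale.

## Known limitations

* Small-strain kinematics only; no contact, no geometric nonlinearity,
  no dynamic effects. Post-fracture softening is therefore not modelled;
  the curve flattens rather than drops, and the 20%-drop rule detects the
  onset of structural yielding.
* The boundary-skin hanging nodes described above.
* Shell elements are membranes without bending or plasticity.
* The DICOM layer reads uncompressed little-endian explicit-VR
  single-frame series only; convert anything richer to NIfTI first.
* Segmentation is a global threshold plus largest component; no
  morphological cleanup.
* The synthetic cohort encodes linear age dependence with Gaussian
  noise; real strength distributions are skewed and heteroscedastic.
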