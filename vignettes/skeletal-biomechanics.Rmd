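---
title: "Methods: volumetric mass properties, joint mobility and retrodeformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric mass properties, joint mobility and retrodeformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomech)
```

This vignette is the package's own account of its methods: the models, the
parameters that matter, the numerical choices, what the synthetic fixtures
do and do not emulate, and the design decisions taken where the problem was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Volumetric body model

### Hoops and lofts

A body segment is an ordered list of octagonal hoops placed along the
skeletal axis. Each hoop lives in the plane perpendicular to its loft axis
and has four cardinal vertices at the lateral semi-axis *a* and
dorso-ventral semi-axis *b* (both cm), plus four diagonal vertices at
k·(±a/√2, ±b/√2). The diagonal factor k interpolates the profile family:

* k = 1/√2 — diamond (diagonal vertices on the inscribed diamond's edges);
* k = 1 — elliptical profile (diagonal vertices on the ellipse);
* k = √2 — rectangle (diagonal vertices at the corners).

The octagon area has the closed form 2√2·k·a·b, which makes entire
segments analytically integrable: between consecutive hoops the loft
linearly interpolates vertices, so every cross-section is again an octagon
with linearly interpolated (a, b), the area is a polynomial in the axial
parameter, and `analytic_hoop_mass_properties()` integrates volume and
centroid exactly. For prisms and uniformly scaled tapers the lofted
*mesh* encloses exactly that volume at any hoop count (the connecting
quads are planar); for non-uniform tapers and curved radius profiles the
mesh converges at second order in hoop spacing, which the test suite
verifies on a quadratic profile. Hoop count and placement are user inputs —
on real material hoops are placed by anatomical judgement, not inferred
from the bones — and the synthetic bodies default to 9 hoops per segment,
within the 8–16 range a practitioner would use.

### Mass properties and cavities

`mass_properties()` computes volume and volume centroid by the divergence
theorem over the faces of a watertight, outward-oriented mesh
(non-watertight input is a hard error naming the open-edge count), and
converts to mass at a configurable density, default 1000 kg m⁻³ — the
standard whole-body density for volumetric reconstructions. Air spaces
(oropharyngeal cavity, lungs) are handled by **mass-property subtraction**
rather than boolean surface operations: for a cavity of volume V_c and
centroid r_c fully contained in a segment (containment is checked),
V ← V − V_c and CoM ← (V·r − V_c·r_c)/(V − V_c). This is exactly
equivalent to the boolean difference and numerically robust; the tests
verify it against explicitly hollowed meshes. Cavity geometry is
config-driven, since published reconstructions rarely give cavity
dimensions machine-readably.

### The sensitivity envelope

Uncertainty about the soft-tissue outline is bracketed by two variants per
segment, applied radially about each hoop's own centre (centres and axes
fixed):

* **maximal** — semi-axes scaled to 120 % of the skeleton-hugging values,
  k set to (1+√2)/2 ≈ 1.2071 (profile halfway between ellipse and square);
* **minimal** — semi-axes unchanged, k set to (1+1/√2)/2 ≈ 0.8536
  (halfway between ellipse and diamond; published rounding prints this
  as 85.3 %).

Both factors are *derived*, not tabulated: the diagonal vertex of the unit
profile sits at radius 1 (ellipse), √2 (square corner) or 1/√2 (diamond
edge midpoint), and the intermediates are the arithmetic means.

Whole-body models combine per-segment variants: all-maximal, all-minimal,
most-cranial mass distribution (maximal neck + trunk + pectoral limbs with
minimal pelvic limbs + tail) and its converse, plus a mean-estimate model
defined as the arithmetic mean of the min- and max-overall models' mass
and CoM. Averaging the two whole-body models (rather than re-lofting mean
segments) is the reading that reproduces the published mean values to
their printed precision, and it is adopted here. The head enters every
model at a single estimate because published segment tables list only one
head row; this package computes that estimate from the unmodified
(skeleton-hugging, elliptical) outline, and the head can still be varied
via configuration. Paired limbs are stored once and mirrored about the
sagittal plane, making the whole-body y-CoM of the paired contributions
*exactly* zero rather than zero to rounding.

The coordinate frame follows the published convention: x cranio-caudal
(cranial positive), y medio-lateral, z dorso-ventral, origin midway
between the hips in the reference pose.

## 2. Joint mobility

### ACS and reference pose

The rotation centre of a ball-like joint is the centre of a least-squares
sphere fitted into a user-selected patch of the proximal articular
surface. The sphere fit is the linear algebraic formulation — exact on
noise-free data for any ≥ 4 non-coplanar points (no full-coverage
requirement, no initialisation, deterministic) — with the geometric RMS
residual reported for diagnostics. Which vertices constitute "the
articular surface" is an anatomical judgement the package deliberately
takes as input rather than guessing.

The ACS axes are the Gram–Schmidt orthonormalisation of three anatomical
direction hints, x first: x is the stylopodium long axis (rotations are
LAR), y points up (pro-/retraction), z cranial (ab-/adduction). All angles
are measured from a non-physiological sprawling reference pose (long axis
perpendicular to the sagittal plane, epicondylar axis horizontal). Sign
conventions, chosen once and documented in the output header: abduction
is +z, adduction −z; protraction −y (the rotation that swings a laterally
pointing long axis cranially), retraction +y; LAR "clockwise" is −x as
seen from the right lateral aspect with cranial to the right.

### Joint space and sweeps

The assumed joint space s (0–2.5 mm by 0.5 mm by default, a proxy for the
vanished cartilage) is realised by translating the mobile bone by s along
the line from the socket centre through the fitted head centre — pushing
it out of the socket — with the rotation centre carried along. The
original studies do not state their mechanism; this is the reading under
which mobility grows with joint space, as every published row pair shows,
and the package's fixtures confirm the monotonicity property. A
consequence worth noting: the *clearance* to the socket rim grows only
second-order in s (the rim remains the closest feature), so joint space
must not be validated by expecting minimum distance to grow linearly.

Each of the six directions is swept independently about its single fixed
ACS axis — no combined rotations — in steps of the angular increment
(default 0.1°, capped at 360° for LAR and 180° otherwise, all
configurable). Collision is mesh intersection, with full containment
counted as collision; the reported maximum is the last collision-free
pose, so results are conservative by at most one increment, and a bone
already colliding at the reference pose reports 0° with a warning flag.
Sweeps are exhaustive from 0° (no bisection): mobility is defined by the
*first* collision, and a non-convex socket can readmit the bone at larger
angles. Identical inputs give bit-identical tables — there is no
randomness anywhere in the sweep.

The tests and the acceptance script run sweeps at 0.5° with a 0.05°
brute-force sweep as the oracle, and fixtures sized at a few thousand
triangles; these sizes keep the whole mobility suite under a couple of
minutes while leaving the increment the dominant error term, and both are
ordinary configuration choices, not limits of the method.

## 3. Retrodeformation

The deformation model is a single global affine map, justified when the
whole bone-bearing stratum deformed homogeneously; the package's
corrections are exact under that assumption and are *not* a substitute
for heterogeneous (spatially varying) retrodeformation. Horizontal
tectonic components are noted but not modelled separately — an affine map
already subsumes them.

* **Rule 1 (shear):** given the anatomical axis triad as fitted in the
  distorted mesh and an orthonormal target triad, the unique affine map
  sending distorted axes onto target axes (origin to origin) is applied.
  For a homogeneous shear this is exactly the inverse deformation, and
  bilateral symmetry returns as a corollary; the tests score symmetry by
  reflecting the corrected vertex cloud through the sagittal plane.
* **Rule 2 (compaction):** a reference cross-section (e.g. a vertebral
  centrum known to be round in life) is extracted as a plane section;
  diameters are measured as extents of the section points along the
  lateral direction and the in-plane perpendicular — deterministic, and
  the operational meaning of a centrum "appearing round" — rather than by
  ellipse fitting. The mesh is stretched along the dorso-ventral axis by
  lateral/dorso-ventral diameter; extents perpendicular to the stretch are
  untouched, and the re-measured roundness must be 1 within 1e-6.
* **Reciprocal cross-check:** a second specimen of the same element
  preserved flat (compacted along its cranio-caudal axis instead) is
  stretched by the *same* rate along its own flattening axis and its
  per-axis extents compared with the expected dimensions, with a
  configurable pass tolerance (default 5 %).

The true dorso-ventral compaction of real material is unknowable without
such circumstantial evidence, so no absolute published rate exists to
target; the fixtures use known distortions (e.g. 0.6) and score exact
recovery (≤ 1e-9 vertex RMS). An optional trilinear-lattice deformer was
considered and rejected: under the homogeneity assumption the affine map
is already exact, and a lattice adds parameters the rules cannot
constrain.

## 4. Synthetic specimens and what passing tests mean

`make_toy_body()`, `make_socket_joint()`, `make_vertebra()` and
`make_skull()` generate every fixture procedurally, each with its ground
truth attached: closed-form volumes and centroids for the body, a
closed-form rim-contact angle for the no-lip cup (shaft cylinder meeting
the inner rim circle), exact inverse transforms for the distortions. The
toy body is scaled to the study conditions — a ~4 kg, ~85 cm quadruped
with a trunk-dominated mass budget. The socket fixture's optional "bony
lip" over the cranial rim sector reproduces the qualitative configuration
in which protraction is blocked long before retraction.

These fixtures certify the *machinery*: integration, collision logic,
transform algebra. They are deliberately not anatomically realistic — a
real glenoid is elongate rather than spherical, real joint surfaces
deviate from the fitted sphere, soft tissues constrain motion well inside
the osteological envelope, and real deformation is never perfectly
homogeneous. Passing tests therefore demonstrate correctness of the
computation, not fidelity of any particular palaeobiological
reconstruction; absolute mobility angles for real material additionally
require the actual bone meshes, which are distributed on request by their
home institutions rather than packaged here. The published whole-body
mass/CoM table, by contrast, is exactly reproducible from its per-segment
rows, and the package does so in its acceptance suite.

## 5. Numerical choices

* Units: cm for geometry, kg for mass; the cm³→m³ factor (1e-6) is applied
  inside `mass_properties()`.
* Watertightness is a hard precondition for mass properties and a soft
  concern elsewhere (distance/intersection queries work on any triangle
  soup; containment semantics additionally need closed surfaces).
* Reflection-like transforms (negative determinant) flip face winding on
  application so meshes stay outward-oriented.
* Triangle–triangle distance is the exact vertex–face / edge–edge
  minimum; intersection is the separating-interval test with an explicit
  coplanar branch; both sit behind a median-split AABB tree. Containment
  is parity ray-casting along a direction chosen to dodge edges, with two
  fallback directions for grazing cases.
* Degenerate inputs error early and specifically: coplanar sphere-fit
  points, singular transforms, empty plane sections, coincident
  socket/head centres, cavities poking out of their segment.
* The loft warns (not errors) when hoop radii change much faster than hoop
  spacing, the regime where a loft can self-intersect.
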