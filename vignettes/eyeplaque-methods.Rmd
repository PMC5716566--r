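---
title: "Methods: TG-43 dose engine and DVH pipeline for eye plaque brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TG-43 dose engine and DVH pipeline for eye plaque brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyeplaque)
```

## The clinical problem

Episcleral plaque brachytherapy treats uveal (ocular) melanoma by suturing a
small concave applicator loaded with low-energy photon-emitting seeds to the
sclera over the tumor base.  The standardized COMS plaque holds its seeds in
a molded silicone carrier; the OSU-NAG design glues fewer seeds directly onto
the shell at simple, ruler-measured coordinates.  `eyeplaque` models both
16 mm plaques over a spherical eye, computes the per-seed air-kerma strength
needed to deliver a prescription to the tumor apex over a finite decaying
implant, and evaluates central-axis dose profiles and tumor dose–volume
histograms (DVHs) so the two loadings can be compared like-for-like.

## Dose model

Each seed is evaluated with the AAPM TG-43U1 two-dimensional line-source
formalism in homogeneous water:

$$\dot D(r,\theta) \;=\; S_K\,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(1\,\mathrm{cm}, 90^\circ)}\, g(r)\, F(r,\theta),$$

where $S_K$ is the air-kerma strength (U; 1 U = 1 µGy·m²/h), $\Lambda$ the
dose-rate constant (cGy·h⁻¹·U⁻¹), $G_L(r,\theta)=\beta/(L r\sin\theta)$ the
line-source geometry factor with $\beta$ the angle subtended by the active
length $L$, $g(r)$ the radial dose function and $F(r,\theta)$ the anisotropy
function.  A plaque dose is the sum of the single-seed kernel over all seeds
(equal strength per seed), each evaluated in its own seed frame.  Interseed
attenuation and the gold-alloy shell are deliberately *not* modeled: the
engine is a homogeneous-water TG-43 calculation of the kind a treatment
planning system performs, not a photon-transport simulation.  The
consequences are discussed under *Limitations*.

### Packaged source models

Two seed models ship with the package, with radial dose functions
transcribed from published Monte Carlo single-source characterizations in a
30 cm water phantom:

| model | radionuclide | $\Lambda$ (cGy/h/U) | active length | half-life |
|---|---|---|---|---|
| `IAI-125A` | I-125 | 0.979 | 0.30 cm | 59.4 d |
| `Cs-1` | Cs-131 | 1.059 | 0.40 cm | 9.689 d |

Half-lives are consensus physical constants stored as ordinary model fields
(overridable through `load_source_model(..., half_life = )`).  The
anisotropy function defaults to a constant-1 sentinel because no tabulated
$F(r,\theta)$ grid is packaged; a published 2D consensus table can be
supplied as an `anisotropy_table()` either programmatically or through the
plain-text parameter-file format (`write_source_model()` /
`read_source_model()`, round-trip exact).  Note that every seed in both
plaques is oriented azimuthally (tangent to its ring), so any point on the
plaque *central axis* sees every seed at $\theta = 90^\circ$ where
$F \equiv 1$ by definition: axis profiles and solved strengths are exactly
independent of the sentinel choice.  Off-axis points — and therefore DVH
tails — are not (see *Limitations*).

### Interpolation choices

* $g(r)$ is interpolated log-linearly (linear in $\log g$ vs $r$), since the
  radial dose function decays quasi-exponentially beyond 1 cm; it is exact
  (bit-identical) at table nodes.  Below the first node (0.1 cm) the first
  value is clamped — those radii are inside or at the capsule surface, where
  extrapolation would be unsupported; beyond the last node (10 cm) the final
  log-linear segment is extended.
* $F(r,\theta)$ is interpolated bilinearly, with $\theta > 90^\circ$ mapped
  to $180^\circ - \theta$ (mirror symmetry of a symmetric seed) and radii
  clamped to the grid.
* The geometry factor uses the exact subtended-angle expression off-axis and
  the closed form $1/(r^2 - L^2/4)$ on the long axis; points on or inside
  the active segment raise an error.  `active_length = 0` selects the exact
  point-source limit $1/r^2$, used by the analytic test fixture.

## Geometry conventions

All user-facing lengths are in mm; seed coordinates and the TG-43 kernel
work in cm internally.  The frame follows the planning convention for
plaques: Z = 0 at the inner sclera beneath the plaque centre, Z increasing
into the eye.  With the default 24.6 mm eyeball and 1.0 mm sclera, the
eyeball centre is at Z = 11.3 mm, the opposite inner retina at Z = 22.6 mm,
and Z = −1 mm is the outer sclera / plaque interface.

The tumor is an ellipsoidal dome anchored at Z = 0 (defaults
12 × 12 × 6 mm), intersected with the eyeball interior: a flat-based dome
necessarily protrudes through the curved sclera near its base rim, and only
the part inside the eye is scored.

Seed centres lie on a sphere concentric with the eye:

* **COMS-16** — 13 seeds: one central, an inner ring of 4 at 3.0 mm
  transverse radius, an outer ring of 8 at 5.8 mm (staggered 22.5°).  The
  seed-centre sphere sits 2.75 mm behind the inner sclera: 1.0 mm sclera
  plus a 1.75 mm offset of the seed-centre plane above the outer sclera,
  reflecting the standard carrier-groove geometry of this plaque.  (A
  shallower choice such as 2.0 mm makes the central-axis falloff
  substantially steeper than published full-plaque calculations; the
  carrier-based 2.75 mm was fixed on construction grounds before any
  comparison and is configurable.)
* **OSU-NAG-16** — 8 seeds in two concentric squares (transverse
  half-diagonals 3.0 mm and 5.5 mm, the outer square rotated 45°).  Seeds
  are glued directly to the shell, so the depth is forced by construction:
  1.0 mm sclera + 0.4 mm seed radius = 1.4 mm.

Orientations are tangential to the seed sphere and tangent to each ring
(azimuthal), matching how elongated seeds rest on a spherical cap.  All
radii, counts, phases and depths are arguments, and a plain-text plaque
configuration format (`read_plaque_config()`) lets transcribed literature
coordinates replace the parametric defaults verbatim.  Geometry generation
is deterministic: identical configuration gives bit-identical coordinates.

## Prescription solving

The default prescription is 85 Gy at 6 mm from the inner sclera (the tumor
apex) over a 6-day implant.  Dose is linear in $S_K$, so the solver is a
single division — no iteration, no tolerance knobs:

$$S_K^{\text{seed}} = \frac{D_{rx}}{\dot d(P)\,\tau}, \qquad
  \tau = \frac{T_{1/2}}{\ln 2}\left(1 - 2^{-T/T_{1/2}}\right),$$

with $\dot d(P)$ the per-unit-strength dose rate at the prescription point
summed over seeds and $\tau$ the effective irradiation time (139.07 h for
I-125 over 6 days, 117.08 h for Cs-131).  Strengths follow the
initial-strength convention: the quoted $S_K$ is the value at implant time.
Re-evaluating the implant with the solved strength reproduces the
prescription at P to machine precision, for every plaque/source combination
— this closure is asserted in the test suite.

## DVH pipeline

Spherical tally cells of 0.5 mm radius are placed on a 1 mm cubic grid
restricted to the region (tumor or eyeball), the paper-and-pencil analogue
of uniform non-overlapping tally spheres.  Numerical conventions:

* **Grid registration.**  x and y run over integer multiples of the
  spacing; the z planes are offset by half a spacing, so one cell centre
  sits on the axis at Z = 0.5 mm and no centre falls exactly on the Z = 0
  region boundary.  Ordering is lexicographic (Z, Y, X) and fully
  deterministic.
* **Volume bookkeeping.**  Each cell represents its 1 mm³ grid voxel, so
  volume fractions equal cell-count fractions and the absolute volume of
  $k$ cells is $k$ mm³.  (Weighting cells by the tally-sphere volume of
  0.524 mm³ instead would shrink the region volume by half and make
  $D_{0.1cc}$ refer to half the tumor — internally inconsistent with
  $V_{200}$-style metrics on the same lattice.)
* **Sampling.**  Dose is evaluated at cell centres rather than averaged
  over the sphere; for 1 mm cells outside the immediate seed neighbourhood
  the difference is well below the other approximations.
* **Metrics.**  $V_x$ is the percentage of cells at or above $x\%$ of the
  prescription dose.  $D_v$ sorts cell doses in decreasing order and
  interpolates linearly within the marginal cell at cumulative volume $v$;
  $v$ equal to the region volume returns the minimum cell dose.

The default tumor lattice has 366 cells (≈ 0.37 cm³ after trimming by the
sclera), so $D_{0.1cc}$ averages over ~100 cells — adequate resolution at
negligible cost.  The whole-eyeball lattice (~6000 cells) is supported for
completeness.

## Synthetic fixtures and what passing tests show

The package tests never download anything.  Fixtures are generated in code:

* `make_toy_source()` — an exactly inverse-square point source
  ($\Lambda = 1$, $g \equiv 1$, $F \equiv 1$), giving closed-form
  expectations for the engine, the strength solver and the DVH pipeline.
* `random_plaque()` — seeded, reproducible scatterings of tangentially
  oriented seeds on a spherical cap, used for property tests.
* `oracle_superpose()` — a deliberately naive scalar re-implementation of
  the TG-43 sum (law-of-cosines subtended angle, its own log-space
  interpolation, no shared helpers) against which the vectorized engine is
  required to agree to better than 1 part in 10¹⁰.

These fixtures exercise the mathematics of the formalism, not the physics
it omits: agreement with the oracle demonstrates that the superposition,
interpolation and normalization are implemented correctly, while agreement
with published full photon-transport results is limited by the model scope
below.

## Limitations

* **Homogeneous water.**  The gold-alloy shell and interseed attenuation
  are not modeled.  Published Monte Carlo studies of these plaques show the
  shell (absorption plus lost backscatter) raises the required source
  strength by roughly 10–20%, with the larger effect when seeds are glued
  directly onto the metal, as in the OSU-NAG design.  Homogeneous-water
  strengths for gold-mounted loadings should therefore be read as lower
  bounds, and plaque-to-plaque *ratios* of normalized doses inherit the
  differential shell effect near the plaque.
* **Anisotropy sentinel.**  With $F \equiv 1$ the dose toward the seed
  poles is overestimated.  Central-axis quantities are unaffected (all
  seeds are seen at $\theta = 90^\circ$ there), but off-axis hot regions
  near the seeds — and hence $V_{150}$/$V_{200}$-type tail metrics — are
  biased high by several volume-percentage points.  Supplying a tabulated
  $F(r,\theta)$ removes this bias.
* **Parametric coordinates.**  Ring radii and depths are reconstructed
  defaults, not manufacturer drawings; sub-millimetre coordinate changes
  move near-plaque doses by several percent.  Exact coordinates can be
  supplied through the configuration format.
* **No radiobiology.**  Dose-rate effects (BED/EQD2) of the faster Cs-131
  delivery are out of scope; the package compares physical dose only.
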