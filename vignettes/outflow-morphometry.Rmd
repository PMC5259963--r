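---
title: "Morphometry and biomechanics of the aqueous outflow pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and biomechanics of the aqueous outflow pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabecula)
```

## The problem

Aqueous humor leaves the eye mainly through the conventional outflow
pathway: it crosses the porous trabecular meshwork (TM) at the iridocorneal
angle, collects in Schlemm's canal (SC), and drains through collector
channels into the aqueous veins. The pressure drop between intraocular
pressure (IOP) and episcleral venous pressure (EVP) drives this flow, and
most of the resistance sits in the TM. Two quantities therefore matter for
understanding ocular hypertension: the depth-resolved *porosity* of the TM
(pore area over valid tissue area in an optical section) and the *caliber*
of the downstream lumina (SC, aqueous vein). `trabecula` implements a
complete, testable pipeline for both, plus a voxel-based reconstruction and
a linear-elastic finite-element model (FEM) of TM deformation under the
IOP-EVP pressure drop.

Because no depth-resolved two-photon stacks of the rat limbus are publicly
deposited, the package ships a synthetic scene generator whose defaults are
calibrated to the measured ranges of the rat drainage pathway. Every
measurement operation is validated by parameter recovery against the
generator's ground-truth labels, and the FEM against analytic oracles.

## The synthetic limbus scene

`default_intact_config()` describes a stack of 27 optical sections of
512 x 512 px at 2 um lateral pitch and 5 um axial step, spanning depths
90-220 um below the eye surface, so the aqueous-vein window (95-120 um),
the TM window (185-215 um) and the SC window (190-215 um) coexist in one
acquisition. In-plane, the cornea lies left of the TM band and the sclera
right of it.

Calibrated defaults (all changeable through `scene_config()`):

* **TM porosity**: linear from 0.63 at 185 um to 0.74 at 215 um (intact);
  0.44 to 0.59 for the broken / high-IOP preset, which models the collapse
  of the meshwork when the pressure balance across it is lost. Both preset
  names (`default_broken_config`, `default_high_iop_config`) denote the same
  reduced-porosity condition.
* **SC**: a signal-void channel inside the sclera whose diameter rises from
  48 um at 190 um depth to a 64.67 um peak at 207 um, falling to 52 um at
  215 um. The cross section is rendered circular (equal major/minor
  diameters) so that the mean centroid chord equals the calibrated diameter;
  the config retains separate major/minor fields for elliptical scenes.
* **Aqueous vein**: a near-axial signal-void tube descending from the
  surface, 32 um wide at 95 um depth to 43 um at 120 um, with a smaller
  (14-18 um) branch. The trunk-branch junction falls between sampled
  sections, so the two appear as disjoint lumina in every slice and the
  largest-component rule always measures the trunk.
* **Beam texture**: TM beams and pores are generated by smoothing white
  Gaussian noise at the beam correlation length (`beam_thickness_mean`,
  default 12 um, i.e. irregular pores a few beam widths across) and marking
  as pore exactly the fraction of lowest-valued pixels given by the
  interpolated porosity target. This order-statistic threshold is the exact
  solution of the "choose a threshold that realizes the target pore
  fraction" problem, so the realized per-slice pore fraction matches the
  profile to within half a pixel of area. Boxes too small to carry the
  texture (fewer than 100 px, or narrower than four correlation lengths)
  are rejected as infeasible.
* **Imaging model**: collagen-bearing classes (cornea 0.95, sclera 1.0,
  TM beam 1.0 relative emission) versus near-zero voids (0.01-0.02); mean
  counts scaled by `photon_scale` (2000) and attenuated by
  `exp(-depth / attenuation_length)` (180 um, a typical scattering length
  scale for sclera at near-infrared excitation); anisotropic Gaussian PSF
  (sigma 2 um lateral, 1 um axial); Poisson shot noise plus Gaussian read
  noise (sd 5 counts). The axial PSF is negligible at the 5 um slice
  spacing, which keeps optical sections statistically independent. The
  generator is deterministic given `seed` (documented default 42).

What the generator does **not** emulate: real beam anatomy (uveal versus
corneoscleral meshwork, juxtacanalicular tissue), refractive distortions,
depth-dependent PSF broadening, curvature of the limbus, or SC collapse
geometry. Passing recovery tests therefore show that the measurement
pipeline is unbiased for scenes with these statistics, not that it is
accurate on any particular real acquisition.

## Porosity estimation

`porosity_profile()` follows the classical flow: crop the valid TM region
(`crop_valid()`), contrast-enhance, derive a segmentation threshold from the
gray histogram, segment, and report the pore-area ratio per depth.

Numerical choices:

* **Enhancement** is a linear 1st-99th percentile stretch onto [0, 1]
  (not adaptive equalization), keeping the histogram interpretable for a
  global threshold. Constant slices raise a classed `tb_degenerate_image`
  error, recorded per slice in the profile's `failed` attribute rather than
  dropped silently.
* **Threshold**: Otsu's between-class-variance maximizer on a 256-bin
  histogram, ties broken toward the lower cut; this is the standard
  deterministic reading of "threshold from the gray histogram". The unit
  tests check it against an exhaustive search over all cut points and
  against an independent implementation.
* **Pores are the below-threshold class** - under two-photon contrast the
  fluid-filled gaps lack signal.
* **One threshold per slice**, not per stack, so the depth-dependent
  attenuation of deep imaging cannot bias deep slices toward
  over-segmentation.
* **Valid area** is the full ROI box; the manual delineation of a "valid
  image" in interactive workflows is replaced by the explicit ROI argument.

A known limitation, surfaced by the property tests: Otsu's criterion is
invariant to *affine* intensity maps (up to re-binning) but not to general
monotone maps. A nonlinear map moves the optimal cut within the inter-class
valley; when blur and noise populate that valley, the estimated porosity can
shift by several hundredths. On well-separated histograms (e.g. noise-free
renders) the shift is bounded by re-quantization and stays below 0.01.

Recovery on the defaults: estimated porosity tracks the ground-truth pore
fraction within 0.01 on noise-free renders and within 0.03 (in practice
about 0.005) on the noisy presets, reproducing the 0.63-0.74 (intact) and
0.44-0.59 (broken) endpoint pairs.

## Lumen diameters

`diameter_profile()` emulates repeated manual caliper measurements
deterministically. Per optical section, `detect_lumen()` takes the largest
below-threshold 8-connected component lying fully inside the ROI
(border-touching components are discarded as truncated; specks smaller than
a 10 um circle, below any reported lumen, are rejected as noise).
`measure_diameter()` then measures the mask extent along `n_repeats = 5`
directions through the component centroid at orientations `0, pi/5, ...`,
and averages them - the reproducible surrogate for "measured five times and
averaged". A chord is the span of hit-pixel centers projected on the ray
plus one pixel footprint, which is exact for axis-aligned chords and within
about one pixel for oblique ones; chords are measured even when the
centroid falls outside a non-convex mask (with a classed warning).

On the intact preset this recovers the SC profile (minimum near 48 um,
maximum near 64.67 um, argmax at 205 um - within one axial step of the
207 um calibration, which falls between sampled sections) and vein
diameters inside the 32-43 um band, always below the SC diameter.

## Reconstruction to a tetrahedral mesh

The reconstruction stage mirrors an interactive segmentation workflow as
replayable code: `threshold_segment()` (tissue is the bright,
at-or-above-threshold class), `region_grow()` (6- or 26-connected component
of a seed), and `morphological_edit()` (close / open / fill_holes with
physical-radius balls, anisotropic in voxels). Every `segmented_volume`
carries its provenance and `replay_provenance()` reproduces it
bit-identically.

`voxel_to_tetmesh()` splits each tissue voxel into 6 tetrahedra by the Kuhn
(Freudenthal) subdivision. Marching-cubes-style surface meshing was
deliberately avoided: the Kuhn mesh conserves tissue volume *exactly*, is
face-conforming across neighboring voxels by construction, and always
produces positively oriented elements - properties the tests assert on
randomized masks. Nodes sit at voxel corners with
`x = col * lateral_pitch`, `y = row * lateral_pitch`, `z = slice *
axial_step` (right-handed, um).

`label_boundaries()` marks boundary triangles whose outward normal lies
within `angle_tol` (default 30 degrees, wide enough to capture the
non-planar TM inner surface facing SC) of the pressure direction as
`pressure`, and triangles inside a user predicate (default reading:
the scleral side face) as `fixed`; where both apply, the constraint wins.
Empty pressure or fixed sets are classed errors - the FEM would otherwise
be unloaded or singular.

One practical caveat: 26-connected growth can keep voxels that touch only
at a vertex or edge; such contacts mesh into rotational mechanisms and a
singular stiffness matrix. For FEM use, grow with 6-connectivity and/or
consolidate with a closing first (the demo in the test suite does both).

## The finite-element model

The TM is modeled as a homogeneous, isotropic, linearly elastic solid
(E = 162 Pa, nu = 0.48 by default) discretized with 4-node constant-strain
tetrahedra - the simplest element for which the voxel mesher is natural and
closed-form oracles exist. Pressure enters as consistent nodal loads
(`p A / 3` per vertex of each loaded face, directed into the tissue);
geometry is converted from um to m at assembly so that Pa-scale moduli and
loads meet SI units, and displacements are reported back in um. Dirichlet
constraints are imposed by row/column elimination, so fixed dofs are
*exactly* zero; constraints are specified per dof (`fixed_dofs()`), which
is what makes roller boundary conditions - and hence an exact uniaxial
patch test for any Poisson ratio - expressible. The reduced SPD system is
solved by sparse Cholesky (Matrix), with a Jacobi-preconditioned conjugate
gradient fallback at 1e-10 tolerance; a relative residual above 1e-8 is a
classed error, not a warning.

`pressure_sweep()` covers the physiological IOP-EVP range 10-160 Pa in
10 Pa steps, reusing one factorization (the solution scales linearly in
pressure), and `deformation_report()` tabulates the maximum absolute
*directional deformation* - the displacement component along the pressure
normal, reported as a magnitude because the loaded surface moves with the
load direction.

Verified properties: exact `p L / E` tip deformation of a roller-supported
bar for nu in {0, 0.3, 0.48}; symmetry of the assembled matrix; exactly six
rigid-body modes before constraint; reaction/load balance to 1e-8;
invariance under node renumbering; strict linearity of the sweep
(deformation at 160 Pa equals 16 times that at 10 Pa).

Physical caveat, reproduced deliberately: with E = 162 Pa and pressures up
to 160 Pa, `p / E` approaches 1, so true strains would be large and the
small-strain assumption is not physically valid at the top of the sweep.
The package reproduces the stated linear model without geometric
nonlinearity; the linear-through-origin pressure response is a property of
that model, not a physiological prediction.

## Problem sizes and determinism

The default synthetic stack is 512 x 512 x 27 voxels and generates in a few
seconds; porosity and diameter profiles take seconds. The FEM verification
suite runs on small box meshes (tens to hundreds of elements) where the
analytic oracles are exact, and the synthetic-TM demonstration mesh is built
from a 32 x 32 x 5-voxel window (a few thousand elements) - large enough to
exhibit beam-scale deformation localization away from the constrained
scleral side, small enough to solve in seconds. All randomness flows from
`scene_config$seed`; label generation and rendering use distinct derived
streams, and the caller's RNG state is restored afterwards.
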