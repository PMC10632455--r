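---
title: "Modelling lesion effects on tDCS electric fields in spherical head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lesion effects on tDCS electric fields in spherical head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfield)
```

## The problem

Transcranial direct current stimulation (tDCS) drives a weak direct current
(typically 1 mA) through the head between two scalp electrodes. The electric
field (E-field) that reaches a cortical target depends on the conductive
anatomy between and around the electrodes, and a brain lesion — a volume of
tissue whose conductivity differs from the grey/white matter it replaces —
distorts that field. `lesionfield` provides a desk-scale pipeline for asking
*how much* and *in which direction* spherical lesions of varying position,
distance, size and conductivity change the field delivered to a spherical
region of interest (ROI), and how electrode montage and stimulator-output
individualisation can compensate.

## The volume-conductor model

Under the quasi-static approximation the potential satisfies

$$\nabla \cdot (\sigma \nabla V) = 0$$

inside the head, with zero current through the free boundary and the
stimulator current injected at the electrodes. The E-field is
$\mathbf{E} = -\nabla V$ (V/m).

The head is a voxelised label volume with seven tissues plus electrode
materials. Default conductivities (S/m): white matter 0.126, grey matter
0.276, CSF 1.65, skull 0.465, skin 0.126, air 2.5e-14, electrode gel 0.3,
electrode conductor 5.9e7. Lesion conductivity is the experimental variable,
varied over 0.2–1.8 S/m, i.e. from roughly grey-matter conductivity to above
CSF. All tissues are isotropic; white-matter anisotropy is out of scope.

### Discretisation

The solver uses a cell-centred finite-volume scheme on the voxel grid: one
unknown per non-air voxel, and for each pair of face-adjacent voxels a face
conductance

$$g_{ij} = h \, \frac{2\sigma_i \sigma_j}{\sigma_i + \sigma_j},$$

the harmonic mean of the two conductivities times the geometric factor
(face area / spacing = voxel edge $h$, in metres). The harmonic mean is the
exact series composition for piecewise-constant conductivity, which is why
the layered-slab fixtures are reproduced to solver precision. The resulting
matrix is a weighted graph Laplacian: symmetric, positive semidefinite, with
zero row sums away from sources (discrete current conservation). A tetrahedral
finite-element pipeline on segmented MRI meshes is the field's standard tool;
the voxel scheme used here is meshless and preserves the quantity of interest
— *relative* lesion-induced field changes — at a fraction of the machinery.

### Current injection, gauge and solver

Each electrode's current (anode positive, cathode negative; the montage must
sum to zero) is distributed uniformly over its conductor voxels. Because the
conductor is several orders of magnitude more conductive than any tissue, the
pad is effectively equipotential and the precise distribution is immaterial.
The singular Laplacian system is gauged by pinning the cathode-centre voxel
to 0 V; since the right-hand side sums to zero the reduced system is
consistent and conservation is preserved exactly. One consequence worth
knowing: swapping anode and cathode moves the reference, so the swapped
potential equals the negated original only up to an additive constant; the
E-field and its magnitude are unaffected.

The reduced symmetric positive-definite system is solved by
Jacobi-preconditioned conjugate gradients (implemented in C++), with a fixed
zero initial guess so that repeated solves are bit-identical. Defaults:
relative residual tolerance 1e-8 (conservation errors far below the
percent-scale lesion effects of interest) and an iteration cap of
$10 \cdot N^{1/3} \cdot 100$. Numerical detail: assembly caps conductivity at
`sigma_cap = 1e4` S/m. The nominal 5.9e7 S/m of the electrode conductor is
physically indistinguishable from 1e4 here (the pad stays equipotential to
within one part in ~3e4 relative to gel) but would degrade the conditioning
of the preconditioned system by three further orders of magnitude.

E-fields are differentiated from the potential by central differences, with
one-sided differences against air boundaries and a zero component in the rare
case of a single-voxel protrusion with no in-domain neighbour along an axis.

## The head phantom

`build_phantom()` voxelises five concentric spheres — skin, skull, CSF, grey
matter, white matter — with default outer radii 92/86/80/78/70 mm, typical
adult head dimensions. Voxels are labelled by centre containment; the default
grid is 2 mm isotropic (1 mm is supported, at eightfold cost). Coordinates
are RAS millimetres with the head centre at the origin, which gives the
direction labels (R, L, A, P, S, I and the eight diagonals) their meaning.

ROIs are 12 mm spheres placed at the grey-matter mid-thickness along a target
direction (the scale of an M1 hand-knob or BA44 target). Disc electrodes
(17 mm radius, 2 mm depth) are rasterised outward from the scalp: one voxel
layer of gel, then conductor.

### The default montage

`montage_for_roi()` places the anode 40° to one side of the target and the
cathode 80° to the other side along a great circle. On a smooth sphere an
anode directly over the target produces an almost purely radial field in the
ROI; real clinical montages (e.g. anode over M1, cathode over the
contralateral orbit) produce a field at the target with a strong tangential
component because of CSF shunting and cortical folding. The straddling,
asymmetric default emulates that: the mean ROI current direction is mostly
tangential with a slight inward dip, and the lesion-angle variable (below)
then covers nearly the full 0–180° range across the valid lesion states
instead of collapsing onto small angles.

## The lesion factorial

Lesions are spheres constrained to grey + white matter, placed relative to
the ROI by direction (14 labels), edge-to-edge distance (1/5/10 mm), radius
(4/12/24 mm) and conductivity (0.2/0.6/1.0/1.4/1.8 S/m): 630 states per ROI,
1260 for two ROIs. The centre is displaced by ROI radius + gap + lesion
radius so the edge-to-edge distance is exact by construction. A state is
excluded when its centre leaves the brain or when less than 20% of the
nominal sphere volume survives the grey/white constraint (threshold
inclusive at exactly 0.20). The volume-fraction denominator is the voxel
count of the unconstrained sphere on an unbounded lattice aligned with the
grid, so spheres partially outside the grid are handled consistently.
Enumeration order is fixed (direction, then distance, then radius, then
conductivity) and conductivity variants of one geometry share a bitwise
identical mask, so result tables are reproducible row for row.

## Outcome measures

For each solved state the pipeline computes, over the grey-matter voxels of
the ROI:

* the voxelwise **difference image** (lesioned minus non-lesioned magnitude),
  summarised by its mean and 16th/84th percentiles. Percentiles use linear
  interpolation between order statistics (type 7), stated so the sort-based
  oracle in the test suite matches exactly. The percentiles are computed on
  the difference image, not on the two magnitude images separately.
* the **percentage difference** `100 * (lesioned mean − baseline mean) /
  baseline mean`. The denominator is the non-lesioned ROI mean; by solver
  linearity this quantity is invariant to the applied current.
* the **lesion angle**: the angle between the ROI-centre→lesion-centre vector
  and the mean current direction in the ROI of the *non-lesioned* brain,
  where the mean direction is the normalised mean of the raw E-vectors (not
  of unit vectors), so coherent strong current dominates. 0° means the lesion
  sits in the path of current; 180° directly opposite.

## Trend models

`fit_trends()` fits ordinary least squares: main effects of distance, size
and conductivity for the absolute percentage difference, plus the angle and
angle×{distance, size, conductivity} interactions for the signed response.
A single phantom has no subject-level grouping, so there is no random effect
to estimate; tables from multiple phantoms/ROIs carry an identifier column so
mixed models can be fitted externally if desired. The planted-effect
generator (`make_planted_table()`) produces tables with known coefficients
and Gaussian noise — the response is approximately normal in the real
factorial too — and the suite checks exact recovery in the noiseless case
and 3-standard-error recovery at noise level 1.

## Montage optimisation and dose individualisation

`optimise_montage()` searches all ordered anode/cathode pairs from a
deterministic Fibonacci-spiral candidate grid on the scalp cap (the phantom
stand-in for a 10-05-style electrode system), solving each pair at fixed
output. Exhaustive search is exact and self-oracling at desk scale (≤ ~64
candidates); ties break to the lowest indices. Two objectives are available:
mean ROI magnitude, and the mean *radial-inward* component (the signed mean
of E projected on the inward cortical normal — on the spherical phantom the
inward normal is simply −r̂). The signed mean is used rather than
rectifying inward-only voxels; that choice is deliberate and documented
here. The component bound (radial objective ≤ magnitude objective) holds by
construction.

`individualise_dose()` applies individualised dose = (target magnitude /
actual magnitude) × fixed dose; by linearity, re-solving at the adjusted
output reproduces the target to solver precision. A configurable
per-electrode safety cap (default 4 mA) is enforced explicitly rather than
inherited from any guideline table.

## Problem sizes used by the shipped checks

The reference checks are sized to run on a laptop-class single core: the
directional check solves the default 92 mm phantom at 2 mm voxels (~0.4 M
unknowns, under a minute per solve); the reduced trend factorial (14
directions × 2 distances × 2 radii × 2 conductivities) runs at 4 mm voxels
(~50 k unknowns, seconds per solve); unit tests use half- and quarter-scale
phantoms. An iterative solution at ≤20³ is cross-checked against a dense
direct solve of the same system.

## What the phantom does and does not show

The spherical phantom preserves the layered conductor structure (skin, skull,
CSF, cortex) and therefore reproduces the robust, monotone findings: lesion
impact on ROI field magnitude grows with lesion size and conductivity
contrast and falls with distance, and the directional spread widens with
each of those factors. A CSF-like lesion in the path of current raises the
ROI magnitude substantially.

One finding does **not** transfer: in real heads, lesions located *opposite*
the current direction (angle near 180°) reduce the ROI magnitude. On the
concentric-sphere phantom a high-conductivity spherical perturbation behaves
like the textbook dipole: the field is *enhanced* near both poles of the
current axis (angle ≈ 0° **and** ≈ 180°) and reduced near the equator
(≈ 90°), a fore–aft symmetry that polarity inversion cannot break. The
measured factorial shows exactly this signature (for 24 mm, 1 mm-distance,
1.8 S/m lesions: +26% at 29°, −19% near 86°, +9% at 138°). The
sign-flip at large angles observed in real anatomy evidently requires
asymmetric anatomy along the current path — gyral folding and the irregular
CSF sheet — that a smooth sphere cannot represent. Analyses of the signed
angle relation on phantoms should therefore be read as a null model, not as
a reproduction of the real-head effect; the monotone absolute-effect trends
are the transferable part.

Other limitations: lesions are geometric spheres, not morphologically
realistic; there is no gyral/sulcal geometry; electrode positions are
spherical-coordinate placements, not 10-05 labels; tissues are isotropic;
and the single-phantom design cannot express between-subject anatomical
variance.
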