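---
title: "mesopaint: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mesopaint: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesopaint)
```

mesopaint builds 2.5D scenes of the cellular mesoscale: molecules are 2D
sprites at physical scale (nm), free to translate and rotate only in the
image plane, distributed over three depth layers, and governed by a
quasi-static rigid-body solver. This vignette records the model, the
parameters that matter, and the places where the design was genuinely open
— what we chose and why.

## Collider inference

Every ingredient gets colliders computed from its sprite contour, never
drawn by hand.

1. **Contour.** The 0.5 iso-level of the alpha channel is traced with
   marching squares (via `grDevices::contourLines` on the zero-padded
   grid). Only the largest closed component is kept; holes and secondary
   blobs are ignored (multi-blob sprites are out of scope). The contour is
   converted to nm, recentred on its vertex centroid, and stored
   counter-clockwise, Y-up.
2. **Eigen frame.** The 2×2 covariance of the contour vertices is
   eigen-decomposed. The major axis carries a deterministic sign
   (non-negative X, ties toward non-negative Y) so identical inputs give
   bit-identical colliders. Degenerate (collinear) contours have λ₂
   clamped to 10⁻¹² nm² with a warning.
3. **Shape choice.** If λ₁/λ₂ < 1.15 the shape is near-isotropic and a
   circle is used, otherwise an oriented rectangle. Two points were
   under-determined and are worth recording:
   - *Ratio versus difference.* A threshold of 1.15 only makes sense as a
     dimensionless ratio: an absolute difference in nm² would flip the
     decision under rescaling, and collider choice must be
     scale-equivariant (a property the tests assert). The
     absolute-difference reading remains available via
     `mp_select_collider(..., mode = "difference")`.
   - *Sizing.* Eigenvalues are nm² while collider sizes are nm, so sizes
     are taken from the projected contour *extents* along the
     eigenvectors (circle radius = max extent on the major axis; rectangle
     = full extents). Eigenvalues decide only the shape and the frame.

Membrane-bound proteins add a second, membrane-only collider group. With
the membrane centerline at `y = -surface_offset` in the sprite frame (the
positive-offset convention: protein center sits *above* the membrane
center; the sprite is always Y-up with its exterior side up), the contour
splits into exterior / intramembrane / interior bands using
`thickness/2 + padding` margins. Each non-empty side gets a fitted
rectangle, and four wheel circles of radius `thickness/2` straddle the
membrane line just outside the main collider (wheel x = ±(main width/2 +
wheel radius)). The wheel radius and x-offset are not prescribed anywhere;
they were chosen so the wheels clear the membrane rectangle edges, which
keeps the railing stable.

Fiber subunits always use a rectangle (width/height = major/minor extents)
plus two end circles of radius = minor half-extent. The end circles sit at
±spacing/2 so that, at rest, consecutive circles coincide — the wording
"positioned around the center at a distance corresponding to the spacing"
could also be read as ±spacing; we chose the reading that makes hinge
anchors coincident at rest and note it here rather than silently.

## The solver

The engine replaces an impulse-based game-physics engine with
position-based dynamics: per step, an optional Brownian kick, then 8
Gauss–Seidel sweeps of (a) pairwise overlap resolution and (b) constraint
projection. There are no velocities; painting is quasi-static, and
determinism (same scene, config, and seed → bit-identical result) falls
out of the fixed iteration order. Choices:

- **Masses.** No masses are prescribed, so mass ∝ collider area, inverse
  inertia ∝ 1/(area · k²) with k² the standard radius-of-gyration formula
  per shape. Locked, pinned, and temporarily frozen bodies are
  infinite-mass.
- **Overlap resolution** moves positions only (no torque), splitting the
  minimum-translation vector by inverse mass. The MTV uses directed
  per-axis depths, which stay correct when one shape is contained in the
  other. Broad phase is sweep-and-prune on x with a 0.5 nm margin.
- **Hinges and pin-to** use the anchored-point response (translation plus
  rotation through generalized inverse masses), so chains bend. Springs
  act center-to-center with a projection fraction of 0.5 per sweep (no
  stiffness given anywhere; 0.5 converges in a few hundred steps without
  overshoot). Hinge angle limits are accepted in the data model but not
  enforced by the solver.
- **Rails.** A membrane protein is projected each sweep onto its chain's
  segment polyline: center at `surface_offset` along the local left
  normal (which faces outward on a clockwise vesicle — that is why
  vesicles are forced clockwise), sprite Y aligned to that normal plus the
  binding rotation, tangential motion free. One consequence of using a
  hard projection: the wheel colliders must not also collide with the
  protein's *own* membrane chain, or the contact pushes the membrane while
  the projection re-centers the protein every sweep and the pair becomes a
  motor that visibly drags the vesicle. Railed proteins therefore ignore
  their own chain; the wheel/box group still collides with every *other*
  membrane. The wheels remain part of the ingredient definition and
  serialization.
- **Collision matrix.** Exposed toggles: protein–protein, fiber–protein,
  fiber–fiber, membrane–membrane (all default on). Unlisted class pairs
  are off by design: the main collider group of a membrane protein
  "collides only with proteins or fibers", and membranes interact only
  through membrane-class fixtures (segments, spacers, wheels, boxes).
  Fiber–membrane separation is enforced when the stroke is drawn (crossing
  strokes are rejected), not by contact forces. Lock hulls collide with
  everything. Layers: the front layer ignores the other layers; the two
  background layers see each other (the only rule stated; we read it
  literally).
- **Diffusion.** Kick variance is `diffusion_scale / sqrt(area)` per step
  (big assemblies jitter less), angular kicks scaled down by a further
  1/area. `diffusion_scale` is an aesthetic free parameter; the default
  0.05 nm²/step makes a 4 nm protein drift visibly in a few hundred steps
  without destabilizing chains. It was fixed before the acceptance
  properties were run and not revisited.

## Strokes, chains, and closure

Stroke paths are resampled by arc length at the subunit spacing (the final
partial segment is dropped — subunits are never stretched). Subunit angles
follow the local tangent plus the cumulative per-subunit twist.
Persistence springs realize the stated counts as spans k = 2…n+1 with rest
length spacing × k; the count is prescribed (DNA 10, RNA 0, membrane 3,
user default 3) but the span *set* is not, and consecutive spans are the
topology that makes "number of springs per subunit" well defined. Closed
chains (circular DNA, vesicles) get wrap-around hinges and springs; whether
rings should carry wrap springs at all is unstated, and we flag the choice
here. Closure uses exactly one segment length as its tolerance. Layer
policy "auto" starts fibers in the front layer and jumps to a seeded random
other layer every 15 subunits ("periodically" quantified); fixed layers are
available. Membranes additionally carry spacer circles (radius =
thickness/2) above and below each segment, enforcing a minimum
inter-membrane distance of twice the spacer radius — values chosen, not
prescribed. Persistence length is deliberately *not* exposed as a direct
parameter; only the preset spring counts are.

## Scene tools

- `mp_paint` runs a bounded local settle (≤50 steps within 3 collider
  diameters) in two phases — first only the new body moves, then the
  neighbourhood relaxes — so the new body takes the push-out and existing
  paint stays put. An unbounded global settle would reproduce a live game
  loop but makes placement order matter at a distance.
- `mp_lock` freezes members, disables their internal collisions, clusters
  centers by flat-kernel mean shift (8 nm bandwidth), and builds one Graham
  hull per cluster. Dilation "by the cluster's largest collider radius" is
  realized by hulling 16-gon samples of each member's bounding circle,
  which guarantees the hull contains whole molecules, not just centers.
  Erasing a locked member recomputes the region's hulls with a notice
  (requiring an unlock first seemed hostile).
- `mp_nudge` moves pinned bodies *with* their pins (an explicit nudge is
  user intent; the alternative leaves the pin behind and snaps the body
  back, which reads as a bug).
- Mean shift uses a flat kernel, 0.01 nm convergence tolerance, 200
  iteration cap, and merges modes within bandwidth/2 — none of these are
  prescribed; they are fixed here and asserted against a
  connected-components oracle in the regime the lock tool sees
  (well-separated clumps).
- Compartment fills of closed vesicles stay dynamic: the interior polygon
  is recomputed from the current segment positions at render and measure
  time, and is triangulated by ear clipping.

## The synthetic fixtures

`mp_fixture_*` generates everything the tests need offline: contours with
analytic eigen-structure (an a:b ellipse has eigenvalue ratio (a/b)²),
pseudo-atom structures with known longest axes (ideal α-helix geometry:
2.3 Å radius, 1.5 Å rise, 100°/residue), strokes with analytic arc length,
a miniature recipe (soluble blob, membrane-bound dumbbell, DNA-like fiber,
membrane segment), and a vesicle demo scene. They emulate the *geometry*
of real inputs, not their content: sprites are flat-shaded, structures are
single-chain pseudo-atoms, and there are no real micrographs. A green test
therefore establishes that the algorithms are implemented as specified —
not that any particular biological scene is accurate, which always
depended on the user's curation.

## Parameters at a glance

| parameter | default | units | notes |
|---|---|---|---|
| eigenvalue threshold | 1.15 | – | circle/rect switch, ratio mode |
| membrane thickness / offset / padding | 4 / 0 / 0.5 | nm | the two "sliders" plus a safety margin |
| fiber spacing | per ingredient | nm | subunit center distance |
| persistence springs | 10 / 0 / 3 / 3 | count | DNA / RNA / membrane / user |
| lock clustering bandwidth | 8 | nm | flat-kernel mean shift |
| solver iterations | 8 | sweeps/step | Gauss–Seidel |
| position tolerance | 0.01 | nm | settle criterion |
| spring stiffness | 0.5 | – | projection fraction per sweep |
| diffusion scale | 0.05 | nm²/step | per unit √area |
| layer-jump period | 15 | subunits | auto fiber layering |
| depth cue | 30% / 60% | – | layers 1 / 2 blend toward background |

## Known limitations

- Sprites with disconnected opaque regions keep only their largest blob's
  contour (the whole image still renders).
- Hinge angle limits are recorded but not enforced.
- mmCIF files load the asymmetric unit only; assembly expansion is
  implemented for PDB REMARK 350 matrices.
- Mirror symmetry of settled scenes holds to the settle tolerance, not
  bitwise: the sweep-and-prune pair order is not mirror-invariant.
- The lock-hull dilation by sampled bounding circles slightly overestimates
  the hull for strongly anisotropic members (their bounding circle, not
  their rectangle, is dilated).
- No undo/redo; erase plus save/restore is the correction workflow.
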