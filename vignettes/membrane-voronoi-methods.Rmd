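---
title: "Per-lipid membrane analysis by periodic Voronoi tessellation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-lipid membrane analysis by periodic Voronoi tessellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidvoro)
```

## The model

A flat lipid bilayer in an orthorhombic periodic box is treated as two
two-dimensional point sets: each lipid contributes one *key atom*
(conventionally the phosphate phosphorus) whose (x, y) position generates a
cell in its leaflet's periodic Voronoi diagram. Two per-lipid observables
follow:

* **Area per lipid (APL)** — the area of the lipid's Voronoi cell, in nm².
  Because the cells of a leaflet partition the box, the leaflet mean APL is
  pinned at `lx·ly / n` whenever no inclusions are present; the *per-lipid*
  scatter around that mean is the signal.
* **Membrane thickness (MT)** — the vertical distance between the lipid's
  key atom and the opposite leaflet's surface, interpolated barycentrically
  on the opposite leaflet's Delaunay triangulation, in nm.

The processing order per frame mirrors the classic membrane-tool pipeline:
leaflet detection, per-leaflet Delaunay triangulation, insertion of
non-membrane atoms and thickness via that triangulation, Voronoi
construction as the Delaunay dual, and APL from the Voronoi cells.

Assumptions baked into this model: the membrane is flat-ish with its normal
along z (the projection plane is xy); boxes are orthorhombic (triclinic
trajectories are rejected, not silently sheared); the membrane is whole
across the z boundary, so no unwrapping in z is attempted. Gently curved
bilayers are handled by the position-based leaflet detector, but strongly
curved membranes and vesicles are out of scope.

## Leaflet detection

Two methods are provided.

**Orientation-based** (`assign_by_orientation`): the sign of the z component
of head − mean(tail terminal atoms). The mean over tails is used so
two-tailed lipids do not depend on an arbitrary tail choice. A lipid with an
exactly horizontal orientation vector is assigned to the upper leaflet with
a warning (ties are a measure-zero event in real data; the tie-break is
documented rather than random).

**Position-based** (`assign_by_position`): a polynomial midsurface
`z = f(x, y)` with all monomials `x^a y^b`, `a + b ≤ d`, is least-squares
fitted (QR, not normal equations) through the key atoms of *all* lipids, and
each lipid is labelled by the sign of `z_key − f(x_key, y_key)`. A single
global fit is used rather than per-leaflet iterative refinement — the
simplest procedure that is exact on every geometry the generator can
produce, including the paraboloid bulge. A residual of exactly zero falls
back to the orientation rule for that lipid, with a warning.

The fit defaults to key atoms only, with an `all_atoms` switch that includes
tail atoms. Key atoms are the cheaper and (in the synthetic geometries)
equally exact choice; the switch exists because fitting all lipid atoms is
an equally defensible reading of what a midsurface should be.

Default degree is `d = 2`: the lowest degree that can follow a single
smooth bulge; on flat membranes the extra coefficients fit ≈ 0 and are
harmless. Degree is exposed on the CLI (`--poly-degree`).

## Periodic tessellation

Periodicity is realized by **ghost replication**: wrapped generators are
copied into the eight neighbouring images within a margin, a Euclidean
Delaunay triangulation (Bowyer–Watson, `src/delaunay.c`) is built over the
extended set, and the Voronoi diagram is taken as its dual — each primary
generator's cell is the polygon of circumcenters of its incident triangles,
ordered by angle. Because every primary generator is surrounded by points,
its cell is finite and convex by construction; no clipping is needed, and
the primary cells partition the box. The constructor verifies
`Σ areas = lx·ly` at 1e−8 relative on every call.

The replication margin defaults to `max(lx, ly)` (full 9-image replication)
below 100 generators and `max(lx, ly)/2` above — small systems are cheap
enough that robustness wins, large ones only need images near the boundary.

Numerical choices, all deterministic:

* Coincident generators are separated by 1e−9 nm before triangulating, in a
  direction keyed on the generator index (hash, not RNG), with a warning.
* The incircle predicate counts points *on* a circumcircle as inside. On
  exactly co-circular inputs (lattices) this keeps the insertion cavity
  star-shaped and yields one of the equivalent degenerate triangulations;
  the Voronoi dual is unaffected because duplicate circumcenters collapse.
  Circumcenters are computed in coordinates translated to a triangle
  vertex, which keeps lattice circumcenters exact in double precision —
  that is what makes the lattice APL exact to 1e−10 rather than merely
  close.
* Insertion order is a fixed pseudo-random permutation (seeded LCG), so
  row-major lattice input does not feed the algorithm long collinear runs.
* Adjacency is defined by a shared Voronoi edge of *positive* length
  (dual edges shorter than 1e−7 nm are dropped). On a square lattice the
  two triangles of each square share one circumcenter, so the diagonal's
  dual edge has length zero: the filter is what makes lattice neighbours
  exactly the four edge-sharing cells, matching the geometric Voronoi
  diagram rather than an arbitrary triangulation of its degeneracies.
* If validation fails, the build retries once with a 1e−11 nm global
  deterministic perturbation before erroring.

## Inclusions

Atoms of residues that match no lipid definition (protein, peptides) are
inserted as extra generators into a leaflet's tessellation when their z
coordinate lies in the slab `[min(z_head) − m, max(z_head) + m]` with
`m = 0.5` nm by default (`--slab-margin`). All atoms in the slab are
inserted, not one per residue — a transmembrane helix should displace cells
along its whole cross-section. Inclusion cells stay in the partition but
are excluded from APL statistics and counted separately in neighbour
profiles, so "mean APL" remains a statement about lipids.

## Thickness

For each lipid, the opposite leaflet's triangulation (over replicated
points, so containment inside the box is guaranteed) is searched for the
triangle containing the lipid's (x, y); the opposite surface height is the
barycentric combination `z1 + λ2(z2−z1) + λ3(z3−z1)`, and
`MT = |z_key − z*|`. This form is exact for constant and affine opposite
surfaces, which is what the exactness checks exploit. Thickness is measured
vertically, not along a local normal — consistent with the flat-membrane
scope, and the two coincide as curvature vanishes. Both leaflets use the
key-atom surface (head-to-head thickness); phosphate-to-phosphate is the
common experimental convention and is what the default `head_atom = "P"`
yields.

Containment uses a barycentric tolerance of −1e−12 with the
lowest-indexed containing triangle on ties (points on shared edges),
relaxing to −1e−8 before declaring a query outside the mesh. A leaflet with
fewer than three lipids cannot be triangulated and is an error.

## Selections

Queries are conjunctions of `field op value` conditions over `resname`,
`leaflet`, `apl`, `thickness`, `neighbors`, `inclusion_neighbors` and
`neighbor_count[RESNAME]`, with operators `== != < <= > >= in`. AND is the
only combinator — unions are expressible as multiple queries — and
selections re-evaluate each frame, so membership tracks the metrics;
`freeze_frame` pins membership to one frame when a fixed cohort is wanted.
Both behaviours are offered because both readings of "track lipids with
certain properties" are useful; neither is claimed to be canonical.

## Rendering

Maps and plots are drawn on a raster canvas with no graphics device, fonts
or locale involved: pixel ownership *is* the minimum-image nearest-generator
rule (exact at pixel resolution), borders appear where ownership changes,
and text uses a built-in 5×7 bitmap font. Identical inputs therefore give
byte-identical PNGs, which the determinism tests assert literally.

Color scales are pinned stop tables: rainbow (blue→red), heated object
(black→red→yellow→white), linear grey, and a 256-entry luminance-monotone
table shipped as `inst/extdata/locs_scale_synthetic.csv`. The latter is a
*synthetic stand-in* constructed to the published design goals of
luminance-optimized scales (luminance rising linearly black→white through
blue/magenta/orange/yellow); the original table is not reproduced here, and
the filename says so. Scale bounds default to the per-frame metric range
and are user-overridable (`--vmin/--vmax`), since fixed bounds are what
make frames comparable.

## Synchronization

Multi-simulation comparison aligns trajectories by integer offset and
stride per trajectory: aligned index k maps to local frame
`offset + k·stride`, missing where a trajectory has no such frame; negative
offsets are allowed. Time-based alignment is a convenience that converts a
ps offset to the nearest frame (half-down rounding, documented) — the
alignment itself is always frame-based.

## The synthetic generator

`generate_bilayer()` is the package's test bed and defines the study
conditions: two leaflets of three-atom lipids (head at the leaflet surface,
two tail atoms 0.5 and 1.0 nm toward the midplane) on an `nx × ny` lattice
with spacing 0.8 nm and head-to-head thickness 4 nm by default — the
packing and thickness scale of a fluid-phase PC bilayer. Gaussian jitter
(σ = 0.05 nm in tests, the scale of thermal positional noise between
frames), an optional paraboloid bulge of total polynomial degree 2 (so a
degree-2 midsurface is exact by construction), an optional fraction of
lipids with tails pointing outward (adversarial for the orientation rule,
invisible to the position rule), and an optional cylindrical PROT inclusion
spanning the bilayer. Randomness uses R's Mersenne–Twister seeded from the
spec; the caller's RNG state is restored, and a fixed seed reproduces every
output file byte for byte.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: conformational disorder (three collinear atoms
are not an acyl chain), water and ions, lipids diffusing across leaflets,
area/thickness fluctuations driven by real dynamics rather than i.i.d.
jitter, and membrane undulations beyond a single quadratic bulge. The tests
establish geometric and algorithmic correctness, not force-field realism.

## Problem sizes and tolerances in the test-suite

The suite runs bilayers of 18–512 lipids and tessellations of up to 256
generators per leaflet with 100 random repetitions, 20 brute-force oracle
instances at n ≤ 32, and 3–30 frame trajectories — sizes chosen so the full
suite completes in well under a minute while still covering every code
path at the acceptance tolerances (1e−8 relative area conservation, 1e−10
lattice exactness, exact thickness on affine references, XTC quantum
0.001 nm at precision 1000).

## Conventions and units

Lengths are nm everywhere internally (PDB Å divided by 10 at the boundary),
areas nm², times ps. Atom and lipid indices are 1-based inside the package
(R's native convention); NDX files are 1-based on disk as the format
requires, and exports print 1-based ids. Frame indices are 0-based, matching
the `--first/--last/--stride` window semantics common to trajectory tools.

## Known limitations

* Flat membranes only: no vesicles, no local-normal thickness, no curvature
  metrics.
* Orthorhombic boxes only; triclinic input errors out.
* The Bowyer–Watson implementation is O(n²) per frame — ample for membrane
  patches (hundreds to thousands of lipids), not for millions of points.
* `.gro`/`.tpr` topologies and velocities/forces in TRR are not read.
* The LOCS-style color table is a documented stand-in, not the published
  table.
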