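---
title: "Detecting access channels by tetrahedral tessellation: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting access channels by tetrahedral tessellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tunneltess` detects channels that connect a protein's surface to a buried
active site, for a ligand of given thickness. This vignette explains the
model and its assumptions, the parameters that matter, what the synthetic
fixtures do and do not emulate, and the choices made where the design was
genuinely open.

## The geometric model

The protein is reduced to its heavy atoms, each a sphere of van der Waals
radius. Their Delaunay tessellation partitions the convex hull into
tetrahedral cells with atoms at the vertices. The triangular face shared
by two cells acts as a *door*: whether a ligand can step from one cell to
its neighbour depends only on whether it fits through that triangle.

The ligand is modelled as a cylinder and, at a door, by its circular
cross-section of diameter CV (its *critical value*, or thickness). A door
admits the ligand iff its width

$$\mathrm{CV}_{\max} \;=\; 2\,\max\!\Big(0,\; \max_{c \in \Delta}\ \min_{i=1,2,3}\big(\lVert c - p_i\rVert - r_i\big)\Big)$$

is at least CV, i.e. iff a disc of diameter CV centred somewhere in the
closed triangle $\Delta$ clears the three vertex spheres. Two modelling
assumptions are deliberate:

* **The disc centre is confined to the closed triangle.** A passage point
  outside the triangle belongs to a different door; allowing it would
  double-count routes that other faces already represent.
* **Only the three vertex atoms obstruct their own door.** Occlusion by
  nearby atoms is carried by the neighbouring doors those atoms define.
  The full passability test of a cylinder with tilt is intentionally not
  solved; the disc model is the package's declared reconstruction, which
  is why comparisons against published channel numbers should always use
  tolerances rather than exact equality.

The *facial graph* has cells as nodes and passable doors as edges, plus
one EXTERIOR super-node attached through every hull face with that face's
own width — a ligand may enter wherever a surface door is wide enough.
The *target* is by default the heme iron; since the iron is itself a
tessellation vertex it has no containing cell, and the arrival region is
its star of incident cells. A *channel* at CV is a connected component
linking EXTERIOR to the target star; the largest CV with a channel is
CV~lim~, a bottleneck (max–min) path value.

Minimal cost paths use the edge cost CV/CV~max~ ∈ (0, 1]: wide doors are
cheap, doors barely wider than the ligand cost almost 1. After Dijkstra
extraction the path's edges are removed and the search repeats, yielding
edge-disjoint alternatives ranked by extraction order.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| vdW radii | Bondi-style table | Å | `vdw_radii()`; replaceable by a key-value file. The published work this reconstructs does not print its radii, a second reason all cross-comparisons carry tolerances. |
| unknown-element radius | 2.0 | Å | fallback, with a warning |
| atom categories | protein + cofactor | — | waters always out; co-crystallized ligands out so channels are computed for the ligand to travel through; heme in, because its iron is the target and its bulk shapes the active-site cavity |
| chain | first chain | — | one chain (plus its cofactor) per analysis |
| working CV | user-supplied | Å | or derived from a named ligand via the cylindrical model |
| degeneracy jitter | 1e-6, seed 20987 | Å | applied only when Qhull reports unrepresentable (co-spherical/coplanar) points; seeded, so reproducible |
| cluster threshold | 0.3 | Jaccard | see below |
| `max_paths` | 20 | — | cap on MCP extraction; the exterior node has as many edges as hull doors, so exhaustive extraction on large structures is rarely informative |
| profile grid | 0.25 | Å | matches the resolution at which channel-opening CVs are conventionally reported |

## Numerical choices

* **Door widths are closed-form.** The clearance field is a minimum of
  three convex functions, so its maximum over the triangle is attained at
  an equal-clearance point of all three atoms (additively weighted
  Voronoi vertex), at an equal-clearance point of two atoms on a triangle
  edge, or at a vertex. All candidates are roots of quadratics; spurious
  roots are harmless because every candidate is evaluated through the
  clearance field. A brute-force barycentric grid oracle (`cvmax_oracle`)
  double-checks this construction in the tests; the field is 1-Lipschitz,
  so a grid of pitch *h* is exact to O(*h*).
* **CV~lim~ twice.** Bisection over the sorted distinct door widths with
  connectivity tests is the production route; a max–min Dijkstra is kept
  as an independent oracle, and the tests require exact agreement.
* **Deterministic tie-breaks.** Dijkstra ties on cost are resolved by
  fewer doors, then by smallest predecessor id — an induction that makes
  the result independent of input ordering. (Full lexicographic path
  comparison would be quadratic; the predecessor-id rule is the package's
  convention.) Channels order by volume descending, then smallest cell
  id.
* **Degenerate inputs.** Collinear door triangles have width 0; coplanar
  tetrahedra volume 0; under-determined point sets (< 4 atoms) are
  errors; co-spherical point sets (e.g. lattice-like coordinates) are
  jittered deterministically and the seed recorded in the result.
* **Tessellation backend.** 3D Delaunay is delegated to Qhull via
  `scipy.spatial.Delaunay` in a subprocess — the de-facto standard,
  robust implementation. The R side builds faces, adjacency, volumes and
  areas, and verifies that cell volumes sum to Qhull's independently
  computed hull volume to a relative 1e-6.

## Clustering MCPs into trajectories

The clustering of minimal cost paths is not dictated by the channel
model, so it is a declared design choice: single-linkage agglomeration,
Jaccard similarity, threshold 0.3 (a configuration knob). The similarity
is computed on the paths' **lining-atom sets** rather than their cell
sets. Cells are maximally fine-grained: two parallel routes through the
same wide mouth can be entirely cell-disjoint — in the limit, a mouth one
cell deep makes *every* pair of extracted paths cell-disjoint — while
threading between the very same atoms. Atom sets are also invariant to
retessellating the same void and are what the method ultimately reports
(lining residues). `metric = "cells"` restores the raw-cell variant.

## The surface-pocket / active-site partition

Published analyses observe that most of a channel system's void lies in
surface pockets. What exactly counts as a surface pocket is unsettled
("part of the protein domain or not"), so the package implements one
explicit, documented rule rather than resolving the question: a cell is
*surface* if it carries a hull face or connects to one through cells that
all keep at least one vertex atom on the convex hull; interior cells
whose vertex set touches the cofactor are *active site*; the rest is
*transit*. Fractions are volume-weighted. The rule is a reconstruction —
treat cross-study comparisons of these fractions accordingly.

## The cylindrical ligand model

The thickness of a ligand is the diameter of its smallest enclosing
cylinder: for each axis direction, project the atom centres on the normal
plane and take the smallest circle enclosing the projected discs (centres
with additive vdW radii — an exact Welzl-type computation); minimize over
directions with a Fibonacci-sphere scan (default 500 directions) refined
by local optimization from the best candidates and the principal axes.
Tests require rigid-motion invariance at 1e-6 Å and < 0.05 Å drift when
the direction grid is doubled. Whether the original convention augments
the cylinder radius by the vdW radii is not documented; both variants are
implemented (`radii_mode = "vdw"` is the default) and the pipeline never
depends on this module when an explicit CV is given.

## What the synthetic fixtures emulate — and what they do not

`make_shell_pore()` builds a quasi-uniform atom shell (Fibonacci
placement, seeded jitter of 0.1 Å recorded in a REMARK) around a central
iron, with one pore framed by three unjittered atoms on a circle of
diameter *a*: that door's width is exactly *a* − 2*r*, giving an analytic
CV~lim~. `make_two_pore()` adds a second, narrower pore at the opposite
pole and an equatorial wall with a 4 Å clearing around the iron. The
clearing radius is chosen so that doors crossing the wall next to the
iron measure well below the narrow pore's clearance while each chamber
keeps wide doors onto the iron's cell star: the two pore systems then
stay cell-disjoint components that both reach the target, and the
channel-appearance profile must show the wide pore first and the narrow
pore as a later, disjoint event.

The fixtures emulate: a buried target, an enclosing atom envelope,
pores of controlled width, multiple disjoint channel systems, labelled
secondary structure at a mouth. They do **not** emulate: realistic atom
packing density in the interior (the shells are hollow, so the "void" is
one huge cavity and every cell touches hull atoms — which is why the
surface-pocket fraction of a shell channel is 1.0), chemical residue
diversity, alternate conformations, or crystallographic artefacts.
Passing the fixture suite therefore demonstrates the correctness of the
geometry and graph machinery and the recovery of known apertures; it
does not by itself validate channel assignments on real proteins, for
which the crystal-structure regression tests exist (they run when local
copies of the published CYP3A4 structures are supplied via
`options(tunneltess.pdb_dir = )`).

Problem sizes used by the test-suite and the acceptance script — shells
of 400–600 atoms (about 900–4000 cells), 100 random doors against the
grid oracle at 5e-3 Å pitch, 30–50 random graphs of up to 12 nodes
against exhaustive search, clouds of up to 200 points for volume
conservation — were chosen as the smallest sizes at which every claimed
property is exercised away from its degenerate limits.

## Known limitations

* The passability test is per-door and planar; a long rigid ligand that
  cannot turn a corner may be declared admissible by a sequence of
  individually passable doors. Conformational flexibility is out of
  scope.
* CV~lim~ and channel shapes inherit the crystal structure's single
  conformation; breathing motions that open or close channels are not
  modelled.
* Channels are reported anonymously with egress elements and lining
  residues; mapping them onto a named channel nomenclature remains a
  curation step.
* The exterior is reached through hull faces of the *convex* hull; for
  deeply invaginated surfaces the mouth of a channel may sit well inside
  the hull, inflating mouth-region volumes (this is visible in the large
  surface-pocket fractions).
* Pores (exterior-to-exterior passages avoiding the target) are detected
  as components but not analyzed further.
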