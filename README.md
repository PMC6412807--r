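# tunneltess

Detection and quantification of ligand access channels to buried protein
active sites, from crystal structures, by tetrahedral tessellation of the
heavy atoms.

Many enzymes — the cytochrome P450 family is the canonical case — bury
their catalytic site deep inside the protein, so every substrate must
thread through a channel from the surface to the active site, and the set
of channels available depends on how thick the ligand is. `tunneltess`
answers, for a given structure and a given ligand thickness: which
channels exist, how large a ligand can still get in, which route is
cheapest, which residues line it, and at which secondary-structure
elements it exits.

## The method

1. **Tessellation.** The heavy atoms (protein plus cofactor; waters and
   co-crystallized ligands excluded by default) are Delaunay-tessellated:
   the convex hull is partitioned into tetrahedral cells with atoms at
   their vertices. Every triangular face between two cells — or between a
   cell and the exterior — is a *door*.
2. **Door widths.** Each door is scored with CV<sub>max</sub>, the
   diameter of the widest disc whose center lies in the closed triangle
   and which clears the van der Waals spheres of the three vertex atoms:

   CV<sub>max</sub> = 2 · max(0, max<sub>c∈Δ</sub> min<sub>i</sub>(‖c − p<sub>i</sub>‖ − r<sub>i</sub>)).

   A ligand modelled as a cylinder of diameter CV passes a door iff
   CV<sub>max</sub> ≥ CV.
3. **Facial graph and channels.** Cells are nodes, passable doors are
   edges; a single EXTERIOR node is attached through every hull door. A
   *channel* at thickness CV is a connected component linking the
   exterior to the active-site cells (the cell star of the target atom,
   by default the heme iron). The largest CV admitting a channel is
   CV<sub>lim</sub>, the bottleneck (widest-path) value; it is computed
   by bisection over door widths and cross-checked with a max-min
   variant of Dijkstra's algorithm.
4. **Minimal cost paths.** Each door costs CV/CV<sub>max</sub> ∈ (0, 1];
   Dijkstra's algorithm yields the minimal cost path (MCP) from the
   exterior to the active site. Removing the edges of each extracted MCP
   and iterating enumerates edge-disjoint alternatives, which are
   clustered (single-linkage, Jaccard similarity on lining atoms) into
   *trajectories* — channels in the usual access-channel nomenclature.
5. **Measures and reporting.** Any set of cells has a volume (sum of
   tetrahedra), a boundary surface (sum of its impassable faces), a
   surface-pocket / active-site / transit partition of its void, lining
   atoms and residues, and egress secondary-structure elements.
6. **Visualization.** Two PDB export modes for any molecular viewer:
   virtual atoms at cell barycenters bonded through passable doors
   (facial-graph view), or the tessellation edges of a region's boundary
   as pseudo-bonds between the original atoms.

A cylindrical ligand model is included: the critical thickness CV of a
ligand is the diameter of its smallest enclosing cylinder over the vdW
spheres, minimized over axis directions (Fibonacci grid plus local
refinement; exact minimum enclosing circle of disks per direction).

## Worked example

The synthetic shell fixture is a jittered atom shell with a buried iron
target and one pore whose door width is known exactly: three frame atoms
on a circle of diameter 8 Å with vdW radius 1.5 Å give a widest clear
disc of 8 − 2·1.5 = 5 Å.

```r
library(tunneltess)
m  <- make_shell_pore(n_atoms = 400, aperture_width = 8, seed = 1)
an <- detect_channels(m, cv = 4.9)
an
#> <channel_analysis> shell_pore_a8_s1
#>   390 atoms tessellated into 906 cells (chain A)
#>   CVlim = 5.000 A; working CV = 4.900 A
#>   1 channel(s) at CV; 1 MCPs in 1 trajectorie(s)
#>   main channel: 774 cells, volume 13888 A^3
#>   void partition: 100% surface pockets, 0% active site

summary(an)$mcps
#>   rank cost n_doors n_cells   volume boundary_surface
#> 1    1 0.98       1       1 100.1599                0

an$trajectories[[1]]$egress
#>    kind label chain first last
#> 1 helix    H1     A   387  389
```

Reading the output: the limiting thickness CV<sub>lim</sub> is recovered
at exactly 5 Å (the analytic pore width); at a working thickness of
4.9 Å there is a single channel whose only entry is the pore door, so one
MCP of one door (cost 4.9/5.0 = 0.98) reaches the target star, and its
egress is the helix annotated on the three pore-frame residues. In a
hollow shell every cell keeps a vertex on the hull, hence the 100%
surface-pocket classification. On a real structure the same call — e.g.
`detect_channels("1TQN.pdb", cv = 6)` — reports the channel system,
CV<sub>lim</sub>, MCP volumes/surfaces, lining residues and egress
elements of the protein.

A thin command-line front end over the same functions is shipped at
`inst/cli/tunneltess.R` (subcommands `analyze`, `cvlim`, `profile`,
`mcps`, `thickness`, `export`, `fixtures`).

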