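---
title: "Quantifying lignin inhibition of cellulases: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lignin inhibition of cellulases: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignocontact)
library(tibble)
```

# The problem

Enzymatic hydrolysis of pretreated lignocellulosic biomass is limited by
lignin: the amorphous aromatic polymer coats cellulose fibrils, blocks the
substrate surface that processive cellobiohydrolases such as *Tr*Cel7A need,
and binds the enzymes themselves unproductively through the very
carbohydrate-binding module (CBM) tyrosines that anchor them to cellulose.
Molecular simulations of crowded cellulose–lignin–cellulase systems make
these mechanisms visible, but only through a specific analysis toolchain:
soft contact statistics, a binding-state taxonomy, interfacial surface
areas, contact networks and aggregate morphologies, and geometric/dynamic
descriptors. `lignocontact` implements that toolchain as a tested, reusable
R package, together with a synthetic biomass generator so that every
estimator can be exercised against known ground truth — the original
multi-million-atom trajectories such analyses were developed on are not
publicly deposited, and no desk-scale package can re-derive their numbers.

# Soft contacts and binding states

The central primitive is the sigmoid-weighted contact number of heavy atom
$i$ in group A against group B,

$$C_i \;=\; \sum_{j \in B} \frac{1}{1 + \exp\!\big[k\,(d_{ij} - d_0)\big]},$$

with steepness $k = 5\ \text{Å}^{-1}$ and midpoint $d_0 = 4$ Å. The weight
is near 1 at hydrogen-bond range, 0.5 at 4 Å, and decays smoothly through
hydrophobic-contact range, so it counts strong short-range interactions with
more weight without a hard cutoff cliff. Only inter-molecular pairs count;
internal molecular contacts are neglected, also when A and B are the same
group. `contact_number()` evaluates the sum with a cell-list neighbour
search truncated at 8 Å, where the weight has decayed to about $2\times
10^{-9}$; the test suite asserts agreement with the untruncated
$O(N^2)$ double sum to $10^{-3}$ relative and with a brute-force truncated
sum to $10^{-9}$ relative on random scenes, with and without periodic
boxes. Distances use the minimum-image convention for orthorhombic boxes.

Binding states use a separate, binary criterion: an enzyme is *bound* to a
molecule class when any of its heavy atoms lies within 3.2 Å of a heavy
atom of another molecule of that class. The three flags (other enzymes E,
cellulose C, lignin L) combine into eight mutually exclusive states
(U, C, L, E, E+C, E+L, L+C, E+C+L); `binding_state_fractions()` reports the
per-frame population of each, and `bound_protein_capacity()` converts a
bound fraction and an enzyme loading (e.g. 230 mg protein per g of
cellulose-plus-lignin solids) into a binding capacity in mg/g. The same
3.2 Å criterion defines contact lifetimes (maximal runs of in-contact
frames, at frame resolution, with events touching the trajectory ends
flagged as censored) and lignin aggregate clustering.

# Gaussian-isosurface areas

Conventional Shrake–Rupley SASA scales poorly to multi-million-atom scenes,
so the package implements the grid-based alternative: every heavy atom
contributes a Gaussian kernel $\exp(-r^2 / 2r'^2)$ of width
$r' = 0.47\,(r_\text{vdW} + 3\ \text{Å})$ — the 3 Å offset absorbs the
hydrogens that heavy-atom-only analyses drop — the kernels are summed on a
grid (1.5 Å spacing in production, truncated at 6 Å where the kernel is
negligible), and the 0.4 level set is triangulated and summed. For an
isolated carbon this gives a sphere of radius
$r'\sqrt{2\ln 2.5} = 2.99$ Å whose area the suite checks against
$4\pi R^2$ within 5 % at a 0.5 Å validation grid.

Two numerical choices deserve note:

* **Level-set triangulation.** Each grid cell is decomposed into the six
  Kuhn tetrahedra sharing the cell's main diagonal and the level set is
  interpolated linearly along crossed edges. The decomposition is identical
  in every cell, so shared faces carry matching diagonals and the mesh is
  watertight (every edge borders exactly two triangles — asserted in the
  tests); extraction has no ambiguous cases and no lookup tables, and is
  deterministic for a fixed grid.
* **Interface definition.** The interfacial area between disjoint groups is
  $I = (S_A + S_B - S_{A\cup B})/2$ on a shared grid lattice, which counts
  buried surface once per partner, is symmetric, and is exactly zero for
  well-separated groups. The tests verify the two-sphere case against an
  exact surface-of-revolution integral of the closed-form density.

`shrake_rupley_sasa()` (deterministic golden-spiral points, 500 per atom,
probe 1.4 Å) is retained as the conventional reference, and
`benchmark_vs_sasa()` reproduces the standard validation: across compact
random selections spanning $10^2$–$10^5$ atoms the two methods correlate
essentially perfectly, with the Gaussian areas a consistent ~10–20 %
smaller because the smooth surfaces glide over the crevices between atoms.
That deficit is a property of the *matter* as well as the method: it grows
with open, corrugated surfaces and can even invert (Gaussian larger than
SASA) for sub-molecular fragments of a few hundred atoms, where overlapping
kernels inflate the smooth envelope. This is why the generator's templates
use heavy-atom-like bonded spacings (1.4–2.6 Å; see below) — on unrealistic
sparse bead models the crevice term dominates and the deficit is far larger
than on real molecules. `coverage_report()` applies the interface machinery
per fibril face, giving the total face area $A_T$, the enzyme and lignin
contact areas $A_E$ and $A_L$, and the coverage ratios $A_E/A_T$, $A_L/A_T$.

# Networks and lignin morphologies

`build_network()` reduces a frame to a molecule-level graph: nodes are
molecules, edges join pairs whose total soft-contact number exceeds a
threshold (default 0.5), weighted by that number. `connectivity_summary()`
reports the component census and per-class degrees — in crowded biomass the
graph is fully interconnected with the fibrils as hubs.

Lignin aggregates are the connected components of the 3.2 Å contact
relation among lignin molecules (`cluster_lignin_aggregates()`, asserted
equal to brute-force components). Their morphology follows operational
rules (`classify_morphology()`):

* contact with **two or more** fibrils → **linkage**;
* else, if at least 80 % of the aggregate's heavy atoms lie within 7 Å of
  the contacted fibril → **sheet** (a monolayer hugging the surface);
* else → **pile**; an aggregate touching no fibril is labelled **free**.

The monolayer distance (7 Å) and layer fraction (0.8) are explicit,
documented thresholds (`morphology_params()`): the three morphologies are
defined pictorially in the literature, so the package states its
quantitative criteria rather than pretending to infer them.
`exposure_per_morphology()` quantifies why the distinction matters: for
equal lignin mass, extended morphologies (sheets, linkages) expose more
non-cellulose-buried surface than compact piles and are therefore the
better enzyme traps.

# Geometry and dynamics

* **Ring stacking** — `crossing_angle()` takes the angle between ring-plane
  normals (from the two leading principal directions of the centred ring
  atoms; exact for planar fixtures), folded to $[0^\circ, 90^\circ]$.
  `stacking_angles()` pairs each tagged CBM tyrosine ring with the nearest
  biomass ring centroid within 5 Å (ties broken toward the smaller
  molecule id, then residue id — deterministic), and
  `random_reference_distribution()` provides the no-preference null: the
  folded angle between independent uniform unit vectors, with analytic
  density $\sin\gamma$ and mean 1 rad $= 57.3^\circ$.
* **Procession lengths** — lignin atoms in 3.2 Å contact with a fibril face
  are projected onto the fibril axis; projected points closer than 5 Å
  merge into occupied intervals, and the gaps between consecutive intervals
  are the distances an enzyme could process before hitting lignin. End gaps
  are excluded (the statistic is defined *between* clusters); a face with
  no lignin contact reports the full span as a single flagged gap.
* **Enzyme orientation** — the angle between the tagged substrate-tunnel
  axis and the fibril axis classifies bound enzymes as parallel
  ($<60^\circ$), antiparallel ($>120^\circ$) or perpendicular; the
  boundaries are declared, as the underlying distributions are published
  without bins. The fibril axis sign is fixed deterministically (largest
  component positive).
* **Diffusion** — `translational_diffusion()` unwraps molecule centroids by
  minimum-image accumulation, averages the squared displacement over time
  origins (pooled over molecules by default; per-molecule mode available),
  and fits $\mathrm{MSD} = 6D\tau + b$ over a stated lag window.
  `rotational_diffusion()` tracks a body-fixed axis through rigid-body
  superposition onto the first frame and fits
  $\langle\Delta\theta^2\rangle = 4 D_r \tau$ in the small-angle regime.

# The synthetic biomass generator

The generator exists so that every estimator can be validated against known
ground truth; its defaults are the study conditions of the system it
emulates.

* **Lignin topologies** (`generate_lignin_topology()`): 61 guaiacyl
  monomers per molecule; linkage composition exactly 50 % β-O-4, 30 % 5-5,
  10 % α-O-4, 10 % β-5 per molecule (largest-remainder rounding of the 60
  linkages); equal left- and right-handed counts for each chiral linkage
  type so molecules are optically inactive; branch points drawn per
  molecule from Binomial(61, 0.052) — the spruce-like crosslink density —
  so the ensemble mean is 3.17 per molecule, realised as a backbone with
  linear branches at distinct interior attachment points (exactly the drawn
  number of degree-≥3 monomers, always a connected acyclic tree).
* **Fibrils** (`generate_fibril()`): 36 glucose chains of degree of
  polymerization 160 by default, on a hexagonal cross-section with 6 Å
  chain spacing and 5.2 Å rise per glucose; crystalline fibrils are
  noise-free, non-crystalline ones add per-monomer Gaussian displacements.
  The two extreme chain rows expose ring planes and are labelled
  hydrophobic; the rest hydrophilic.
* **Pseudo-enzymes** (`generate_pseudo_enzyme()`): a globular catalytic
  domain with two beads defining the substrate-tunnel axis, an
  O-glycosylated linker whose sugars are residues of their own, and a CBM
  presenting three flat tyrosine rings tagged 466/492/493.
* **Templates** are deliberately at heavy-atom-like packing (bonded
  spacings 1.4–2.6 Å; glucose 9 atoms, guaiacyl 15 atoms matching the
  ring/chain atom classes C1–C6/O3/O4/C10 vs C7–C9/O7–O9, enzyme beads at
  2.3 Å): surface areas — and especially the Gaussian-vs-SASA deficit — are
  sensitive to atomic packing density, and sparse bead models would
  misrepresent the method's behaviour on real matter.
* **Scenes** (`assemble_scene()`): fibrils laid in parallel; lignin
  aggregates *constructed* to satisfy the requested morphology (flat walks
  confined to a face for sheets, centroid-biased compact walks for piles,
  extended walks spanning two fibril tops for linkages), then slid into the
  2–3.2 Å contact window; enzymes dropped at random positions and
  orientations and re-drawn until free of steric clashes (minimum
  inter-molecular heavy-atom distance 2 Å, asserted by brute force in the
  tests), exactly the rejection scheme used to build such models. Placement
  failure raises an error naming the molecule.
* **Brownian trajectories** (`generate_brownian_trajectory()`): rigid-body
  dynamics with per-axis translational steps $\mathcal{N}(0, 2D\,\Delta t)$
  and rotations composed about the three laboratory axes with per-axis
  angle variance $2 D_r \Delta t$, which realises isotropic rotational
  diffusion with $\langle\Delta\theta^2\rangle = 4 D_r t$ for a body-fixed
  axis — the same convention the estimator fits, so parameter recovery is a
  clean closed loop. (A single random-axis step of variance $4D_r\Delta t$,
  an alternative sometimes written down, tilts a fixed axis by only 2/3 of
  that variance and would make the estimator look 33 % biased; the
  three-axis composition is the consistent convention.) Coordinates are
  wrapped by molecule centroid, so trajectories remain unwrappable;
  steps so large that 5σ exceeds a quarter box are rejected as unphysical.

Defaults for diffusion fixtures follow the physical regime of enzymes in
crowded biomass: translational constants from $10^{-6}$ cm²/s (free
protein) down to $10^{-9}$ cm²/s (trapped), rotational constants
$10^{6}$–$10^{5}$ rad²/s, 1 ns frames. The validation suite recovers
translational constants within 10 % across those three decades and
rotational constants within 15 % from 2000-frame trajectories pooled over
12 molecules — sizes chosen so the statistical error of the MSD slope is a
few percent, well inside the tolerances being asserted.

What the generator does *not* emulate: solvent and hydrodynamics,
force-field energetics, atomistic lignin 3D chemistry (the embedding is a
self-avoiding walk over the real bonding topology), enzyme conformational
change, and the slow aggregation kinetics that produce morphology mixtures
in long simulations. Passing tests therefore demonstrate that the
*estimators* are correct and well-calibrated on data with known truth — not
that any particular biological number is reproduced; trajectory-derived
quantities from the original systems (binding fractions, interface-area
magnitudes, procession lengths, compaction radii) are out of reach without
those trajectories.

# Degenerate inputs and edge conventions

Empty atom groups give zero contact results with a warning; an iso level
outside the grid range gives an empty mesh with a warning; enzymes bound to
nothing are state U; a lignin-free face reports its full span as a flagged
procession gap; near-linear molecules are rejected by the rotational
estimator (their axis spin is unobservable); chirality balancing with an
odd count leaves the odd linkage's hand random; molecule-pair keys are
always unordered with the smaller id first.

# Problem sizes

The shipped validation uses desk-scale inputs chosen once: random contact
scenes of up to 500 atoms (50 replicates against the brute-force oracle),
surface validation at a 0.5 Å grid on single atoms and two-sphere fixtures,
morphology scenes of two 12-chain × 24-monomer fibrils with three
aggregates, diffusion fixtures of 12 rigid molecules × 2000 frames, and
topology ensembles of 1000 molecules. The acceptance script scales the
surface benchmark up to a ~186,000-atom scene with selections of $10^2$ to
$10^5$ atoms at the 1.5 Å production grid.
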