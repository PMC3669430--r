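---
title: "The hybrid MM/CG model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid MM/CG model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcg)
```

## The model

mmcg simulates membrane receptor–ligand complexes with a hybrid
resolution scheme. The chemistry that matters for binding — the ligand,
the binding-cavity residues and a droplet of water around them — is
treated atomistically (the **MM** region); the rest of the protein frame
is a structure-based coarse-grained model with one bead per residue on
the C$\alpha$ (the **CG** region); an **interface** (I) region bridges
the two. The membrane is implicit: a set of confining walls replaces the
lipids. This cuts the number of degrees of freedom by orders of
magnitude while keeping the binding site fully atomistic.

### Region partition

The MM protein residues are given explicitly (the cavity-lining
residues). Every other protein residue whose minimum heavy-atom distance
to the MM boundary — the MM protein residues plus the ligand — is at
most the interface cutoff (default 6 Å) becomes I; the remainder is CG.
Ligand and water are MM unconditionally. Three choices here are ours,
because the distance rule alone does not fix them:

* membership is decided **per residue** using **heavy atoms** only
  (hydrogens carry no excluded volume of their own and their positions
  are force-field artifacts);
* the mobile solvent does **not** define the MM boundary — a droplet
  whose 15 Å radius spans the entire structure would otherwise promote
  every residue to I and leave nothing coarse-grained;
* the partition is computed once from the starting structure and held
  fixed for the whole run (production systems use fixed residue lists).

### Atomistic terms

The MM and I regions use the standard fixed functional forms: harmonic
bonds $E = \tfrac{k_b}{2}(r - r_0)^2$, harmonic angles
$E = \tfrac{k_\theta}{2}(\theta - \theta_0)^2$, periodic dihedrals
$E = k_d (1 + \cos(n\varphi - \delta))$, 12-6 Lennard-Jones with
Lorentz–Berthelot mixing, and Coulomb with
$k_e = 1389.35458$ kJ mol$^{-1}$ Å e$^{-2}$ and dielectric 1 (the
explicit water carries the screening). All pair interactions are
truncated at 16 Å with the pair energy continuous (zero) at the cutoff;
no reaction field, no Ewald. Lennard-Jones uses a plain energy shift (its
force at 16 Å is negligible), while Coulomb uses **shifted-force**
truncation, $E = k_e q_i q_j (1/r - 1/r_c + (r - r_c)/r_c^2)$, so the
pair force also vanishes at the cutoff: with an energy shift alone, every
charged pair crossing 16 Å receives an O(1 kJ/mol/Å) force jump, and the
accumulated jumps measurably violate energy conservation. 1-2 and 1-3 pairs are excluded; 1-4
pairs are included at full strength by default (configurable), computed
unshifted like the bonded terms they accompany. Water is the 3-site SPC
model (O–H 1.0 Å, 109.47°, $q_O = -0.82$, $q_H = +0.41$,
$\sigma_O = 3.166$ Å, $\varepsilon_O = 0.650$ kJ/mol), rigid through
constraints; the polar hydrogens (water H, the ligand's N–H) carry a
small Lennard-Jones site ($\sigma = 1.2$ Å, $\varepsilon = 0.1$ kJ/mol)
that caps the Coulomb singularity of a bare point charge. When
constraints are disabled (microcanonical checks), water becomes flexible
with deliberately soft springs ($k_b = 400$ kJ mol$^{-1}$ Å$^{-2}$,
$k_\theta = 100$ kJ mol$^{-1}$ rad$^{-2}$): these springs exist *only*
in the unconstrained variant — production water is rigid and never sees
them — and softer modes keep $\omega\Delta t$ small enough that the
velocity-Verlet shadow-energy oscillation stays well below the drift
tolerance. Parameters are data, read from a version-stamped YAML file;
the package ships a small toy set (`toy_parameters()`) for the synthetic
systems — the method, not a particular parameter database, is what the
package implements.

### The Go-like CG model

The CG (and I) residues define beads on their C$\alpha$ positions.
Sequence-adjacent beads of the same chain are joined by stiff harmonic
"chain bonds" at their native distance ($k = 1000$ kJ mol$^{-1}$
Å$^{-2}$). Residue pairs with sequence separation $\ge 3$ whose native
structure has any heavy-atom pair within 4.5 Å form a **native
contact**, modelled by the 12-10 well

$$E(r) = \varepsilon_{go}\left[5\left(\frac{r_{nat}}{r}\right)^{12} -
6\left(\frac{r_{nat}}{r}\right)^{10}\right],$$

with its minimum $-\varepsilon_{go}$ at the native C$\alpha$ distance.
All other bead pairs repel as $(\sigma_{rep}/r)^{12}$ with
$\sigma_{rep} = 4$ Å, except sequence-local pairs (separation $\le 2$,
carried by the bonded structure) and the atoms of contacting residue
pairs (a native pair interacts through its well only, as in standard
structure-based models).

The well depth deserves a note. With kT $\approx 2.5$ kJ/mol at 300 K, a
well of order 1 kJ/mol is above its own folding temperature: contacts
melt and the model does not preserve the fold, which is its entire
purpose here. Densely packed proteins have roughly 3 contacts per
residue, so conventional depths near 1 kcal/mol provide
$\sim$12 kJ/mol of stabilization per residue. The minimal toy bundles
this package tests on have sparse maps ($\sim$0.4 contacts per bead), so
the default depth is $\varepsilon_{go} = 16$ kJ/mol — per residue still
only about half the stabilization of a conventional model, but enough
that the native state is the thermally dominant minimum. The depth is a
plain parameter for real systems.

### Interface coupling

I-region atoms are evaluated by the full MM force field alongside the MM
region. Their C$\alpha$s additionally carry the complete Go bonded
network — chain bonds and contacts, to CG beads and to each other — so
the two resolutions overlap across the interface rather than abutting; a
Go chain bond is dropped only where the same C$\alpha$ pair already has
an atomistic backbone bond. Pure CG beads see atomistic particles only
through the soft $(\sigma_{rep}/r)^{12}$ repulsion (heavy atoms only),
which prevents inter-resolution overlap without inventing mixed
electrostatics. The exact interface Hamiltonian is a genuinely open
design point; this choice keeps each resolution's internal physics
intact and is the weakest-coupling option that still transmits excluded
volume.

### Implicit membrane and droplet walls

All walls are half-harmonic: $E = \tfrac{k}{2} d^2$ for penetration
depth $d$ beyond the surface, zero inside, $C^1$ at the surface
(stiffness 250 kJ mol$^{-1}$ Å$^{-2}$, chosen so thermal penetration at
300 K stays well under 2 Å — verified by the containment test).

* **Planar slab walls** at the lipid-head heights,
  `slab_center ± 31/2` Å, confine the membrane-zone protein particles in
  z, and (optionally, on by default for the toys) keep water oxygens on
  the extracellular side of the upper plane — that is the physical role
  of the lipid-head plane in a droplet setup.
* The **lateral membrane wall** follows the initial protein–membrane
  interface: the allowed region is the union of spheres of radius 2.0 Å
  around the initial membrane-zone C$\alpha$ positions. This reproduces
  "follows the initial shape" without any mesh machinery. The distance to
  the union surface is evaluated as a log-sum-exp soft minimum
  ($\beta = 10$ Å$^{-1}$) over the anchor distances: a hard minimum has a
  force discontinuity across anchor Voronoi boundaries that leaks energy
  in microcanonical runs; the soft minimum is C$^1$, coincides with the
  hard minimum for a single anchor and sits within $\sim$0.1 Å of it
  otherwise.
* **Hemispheric caps** cover protein particles initially beyond the
  planar walls, with radii at the 95th percentile of the distances to
  the respective end centroid plus a 5 Å margin. Particle sets are fixed
  at build time from the initial z coordinates, so no particle switches
  walls mid-run.
* The **droplet wall** confines water oxygens (hydrogens follow through
  the rigid-water constraints) to a 15 Å sphere centred, by default, on
  the instantaneous ligand centroid. A moving centre makes the energy
  depend on the ligand coordinates; the reaction force on the ligand is
  included so forces stay exact gradients — the finite-difference tests
  cover exactly this term.

If the structure's bundle axis (mean of per-chain C$\alpha$ end-to-end
directions) is more than 30° from z, the builder warns and auto-aligns.

### Dynamics

Stochastic dynamics at 300 K uses the symmetric BAOAB splitting: half
kick, half drift, an exact Ornstein–Uhlenbeck velocity update
$v \leftarrow e^{-\gamma\Delta t} v + \sqrt{1 - e^{-2\gamma\Delta t}}
\sqrt{kT/m}\,\xi$, half drift, half kick. The friction is
$\gamma = 1/\tau$ with $\tau = 0.4$ ps — the "inverse friction constant"
of the production protocol, whose units of ps force the relaxation-time
reading. With $\gamma = 0$ the scheme reduces to velocity Verlet, which
is how the energy-conservation test runs. SHAKE projects positions onto
the constraint manifold after every drift (tolerance $10^{-4}$ relative,
enforced with margin) and a RATTLE projection removes constraint-violating
velocity components after every kick. Constraints cover every bond
containing hydrogen plus fully rigid water (two O–H and one H–H distance
per molecule). The timestep default is 0.002 ps with constraints —
standard practice; the production protocol leaves it open.
Centre-of-mass motion is removed every step by default so the system
cannot drift against its fixed walls; the kinetic temperature uses
$N_{df} = 3N - N_c - 3$ accordingly.

Randomness is counter-based: step $k$ of a run draws from an RNG stream
keyed by (seed, $k$), so trajectories are bit-reproducible, single steps
compose exactly into runs, and replicas simply use seed + replica − 1.
Replica trajectories are analysed jointly by frame concatenation.

### Preparation

`prepare_system()` minimizes the assembled system (constraint-aware
steepest descent with a 0.2 Å trust radius), refits the Go reference
distances to the relaxed structure, and minimizes briefly again. An
idealized construction geometry is never exactly a minimum of the full
potential; using the relaxed structure as the native reference removes
that systematic strain, just as experimental structures are
energy-minimized before production runs.

## Analysis layer

Superposition is the Kabsch least-squares fit (proper rotation enforced)
via the SVD. The C$\alpha$ RMSD series supports a residue exclusion
applied to both fit and measurement (for mobile loops). Ligand-pose
clustering first aligns every frame's protein C$\alpha$s to frame 1 and
then measures the ligand-atom RMSD *without* refitting — the pose, not
just the conformation; the greedy largest-neighborhood algorithm with a
1 Å cutoff extracts clusters, ties broken by the lowest frame index (the
algorithm itself leaves ties open), populations as member fractions.
Hydrogen bonds use the common geometric definition, donor–acceptor
$\le 3.5$ Å and D–H⋯A $\ge 130°$, both configurable; distances are
reported regardless of the angle so distance distributions do not depend
on the angle choice. Distance tables use the centroid convention for
ring and side-chain selections (recorded in the output metadata, since
"ring–ring distance" alone does not fix a convention). All analyses are
deterministic; the alignment reference is frame 1 of the joined
trajectory.

## The synthetic toy systems

`make_toy_bundle()` builds ideal vertical α-helices (rise 1.5 Å, 100°
per residue, C$\alpha$ radius 2.3 Å), each residue carrying a C$\alpha$
and one pseudo side-chain atom CB placed 1.9 Å radially outward from the
bundle axis — side chains line the outer surface, the core stays open,
and neighbouring helices sit close enough (axis circle radius
`cavity_radius + 0.2` Å) to form native contacts without steric clash
(the generator enforces $\ge 1.5$ Å between non-bonded heavy atoms). The
ligand is a planar six-carbon ring with an N–S polar head and an N–H
donor — ring + thioamide chemistry at toy scale — placed on the bundle
axis at the extracellular mouth, at the lowest height with 3.2 Å
clearance (outside the steep part of the LJ wall). The bundle stands
with its mouth at the upper lipid-head plane: membrane slab below,
droplet dome above, which is where `solvate_droplet()` places its rigid
SPC waters by rejection sampling (uniform in the dome, $\ge 2.4$ Å from
any existing heavy atom, random rigid orientations, deterministic per
seed).

What the toys do *not* emulate: real side-chain packing density (hence
the deeper contact wells discussed above), sequence chemistry, a ligand
that binds strongly enough to stay caged for long runs, or anything
approaching production length scales. Passing the test battery
demonstrates that the machinery — forces, constraints, thermostat,
walls, clustering — is correct, not that the toy is a receptor.

`make_reference_trajectory()` constructs analysis inputs with known
ground truth: `static`, `two_pose_switch` (exactly two pose clusters
with preset populations), and `random_walk` with displacements clipped
at $3\sigma$ so a single cluster at the 1 Å cutoff is guaranteed by
construction.

## Numerical choices

* Verlet pair list with a 2 Å skin, rebuilt on half-skin displacement;
  result-identical to the brute-force pair sum (tested exactly).
* Minimizer: steepest descent with backtracking; accepted moves are
  SHAKE-projected so rigid water survives minimization.
* SHAKE convergence criterion is set a factor of a few inside the
  stated tolerance so the post-step deviation always satisfies it.
* Degenerate geometry fails loudly: zero-length bonds, coincident
  beads, collinear superposition selections and overlapping nonbonded
  atoms are errors, not NaNs.
* Problem sizes in the shipped tests: the standard toy (4×10 residues,
  9-atom ligand, 60 waters, ~250 particles) runs $10^5$ steps for the
  stability/containment/temperature checks and $10^4$ microcanonical
  steps for conservation; thermostat statistics use $10^4$ velocity
  samples and a $10^5$-step single-particle series.

## Known limitations

* No Ewald/reaction-field electrostatics; shifted truncation only.
* The interface Hamiltonian is one defensible choice among several; CG
  beads carry no charges, so long-range CG–MM electrostatics is absent
  by construction.
* The lateral wall constrains the protein to the union of spheres
  around its initial C$\alpha$ path; sliding *along* that surface is
  unpenalized, so global confinement is looser than a per-particle
  restraint.
* Only 3-site rigid water; no polarizable or 4-site models.
* The CLI and pipeline target the synthetic systems; external PDB input
  is supported, but parameters for arbitrary chemistries must be
  supplied by the user.
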