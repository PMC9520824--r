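---
title: "Coarse-grained annealing of multivalent ligands on affinity grids"
author: "annealbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained annealing of multivalent ligands on affinity grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annealbind)
```

## The problem

Large, flexible, multivalent charged ligands — for example a symmetric
chain carrying two cationic guanidiniocarbonyl-pyrrole (GCP) arms, two
lysines and a central aggregation-induced-emission (AIE) luminophore — do
not bind a protein at a single well-defined pocket the way small rigid
ligands do. Their binding is dominated by long-range electrostatics,
multivalent avidity and conformational entropy, so docking tools built
around rigid pockets are a poor fit. `annealbind` takes the opposite
route: represent the ligand as coarsely as its physics allows, represent
the protein only through precomputed interaction fields, and then
characterize the *ensemble* of low-energy poses rather than a single
docked structure.

## The model

**Ligand.** A chain of five beads, GCP–Lys–AIE–Lys–GCP. Consecutive beads
are joined by harmonic springs,

$$E_\text{spring} = \tfrac12 \sum_{i=1}^{4} k_i\,(l_i - l_i^\text{eq})^2 ,$$

and every non-bonded bead pair repels as a hard sphere: the energy is
$+\infty$ when their distance $d < a$ and $0$ for $d \ge a$. The default
parameterization (from an atomistic model of the ligand) is
$l^\text{eq}_{1,4} = 6$ Å (GCP–Lys), $l^\text{eq}_{2,3} = 13$ Å
(Lys–AIE), $k_{1,4} = 12\,k_BT/\text{Å}^2$, $k_{2,3} = 3\,k_BT/\text{Å}^2$
and $a = 9.6$ Å. Spring constants given in $k_BT$ units are converted to
kJ/mol once, at a fixed reference temperature (default 300 K); the
Hamiltonian does **not** rescale with the annealing temperature — a
temperature-dependent energy would break the Metropolis criterion's
detailed balance at each level.

**Protein.** The protein enters only through per-fragment affinity grids:
regular lattices (production spacing 0.4 Å) whose nodes hold the
interaction energy of a GCP or lysine fragment at that position, plus a
steric mask flagging every node inside an atom's van der Waals radius as
forbidden ($+\infty$). The total energy of a conformation is

$$E_\text{total} = E_\text{spring} + E_g^\text{GCP1} + E_g^\text{Lys1}
  + E_g^\text{Lys2} + E_g^\text{GCP2},$$

with the AIE bead contributing no grid term. Beads live on grid nodes
(moves are defined in grid lengths); distances are Cartesian.

Affinity grids can be read from OpenDX files produced by external
Poisson–Boltzmann/probe-scanning pipelines, or generated internally:
`dhPotentialGrid()` builds a screened-Coulomb (Debye–Hückel) potential by
superposition over PQR atoms, and `probeScan()` converts a potential into
an affinity map by averaging a rigid multi-atom probe over quasi-uniform
random rotations. The built-in potential is deliberately simple — no
dielectric boundary (the protein permittivity parameter is accepted but
unused), no desolvation, screening attenuated outside each atom's radius
— and is intended for self-contained testing and qualitative maps, not as
a replacement for a nonlinear PB solve.

## The search

Each run anchors the AIE bead at a node drawn from a *placement layer* —
all allowed nodes within 19 Å (the chain distance from AIE to GCP) of the
protein's van der Waals surface — and then anneals the remaining four
beads:

* Metropolis MCMC at each temperature level; a level ends after 10000
  proposals or 1000 acceptances, whichever comes first.
* Geometric cooling from 3000 K with factor 0.95 per level (the cooling
  law itself is our choice; only "slow cooling" is prescribed by the
  protocol the package implements).
* A proposal displaces one uniformly chosen mobile bead by an integer
  vector with components uniform on $\{-m,\dots,m\}$ grid lengths.
* The run stops after the first level whose acceptance ratio
  (acceptances / proposals of that level) falls below 1%, or after 200
  levels — a safeguard for landscapes where zero-cost moves keep the
  ratio high forever.
* The production ensemble is 4000 runs; per-run seeds derive from the
  master seed so results are reproducible and order-independent.

The hot loop (propose / evaluate / accept) is compiled code; its energy
arithmetic is mirrored exactly by the R-level `totalEnergy()`, and every
stored result re-evaluates its final conformation through the R path, so
any divergence between the two implementations would surface immediately
in the recorded energies.

### Move extent on coarse grids

The displacement cap is stated in grid lengths: 6 on the production
0.4 Å grid, i.e. a 2.4 Å physical extent. On the coarse grids used for
oracle validation (3 Å spacing) keeping "6 grid lengths" would mean 18 Å
jumps; the springs veto almost all such proposals, the acceptance ratio
sits near the 1% stop even at 3000 K, and runs terminate as hot, unequilibrated
snapshots. `moveCapForSpacing()` therefore preserves the *physical*
extent, with a floor of two grid lengths: below that, the probability of
proposing a zero displacement ($1/(2m+1)^3$, a legal proposal that always
passes Metropolis) exceeds the 1% stop threshold and the run could never
terminate by the acceptance rule. The production default is unchanged;
the cap only adapts when the package is used at coarse spacings.

## Analysis

`energyHistogram()` summarizes final ensemble energies (log-scaling
applies to counts). `minEnergyConformations()` ranks runs by final energy
with ties broken by run index. `clusterMedoids()` partitions the final
AIE positions of the lowest-energy fraction of runs (default: lowest 5%,
ties included — on symmetric systems whole groups of runs are exactly
degenerate) around medoids; `k` can be fixed or chosen in $[2, 10]$ by
average silhouette width. `c2SymmetryScore()` quantifies two-fold
symmetry of a pose set as the median distance from each 180°-rotated
point to its nearest original point, in Å: 0 for a perfectly symmetric
set, $2r$ for a single point at distance $r$ from the axis. The axis is
supplied by the user (for a homodimer: through the central pore); the
package does not infer biological symmetry axes. `contactReport()` lists
protein residues within a cutoff (default 5 Å) of any bead center.

## Synthetic validation systems

Real production grids require an external structure and a PB solve, so
the package ships generators that make the whole stack testable from
nothing:

* `makeToyProtein()` — spheres, planes and exactly C2-symmetric two-lobe
  structures with declared axes.
* `makePlantedMinimumInstance()` — a compact toy protein carves a steric
  mask at the center of a 15³-node, 3 Å grid; the GCP and Lys grids are
  zero-mean Gaussian noise (default $\sigma = 0.5$ kJ/mol) plus Gaussian
  wells of one-node half-width planted at nodes the default ligand can
  reach (spring strain within 3 Å of equilibrium, all hard-core
  separations satisfied). Default well depths are $-60$ kJ/mol jittered
  ±20% per instance — deep enough that the global minimum is unambiguous
  against the noise floor, shallow enough that the spring penalty of
  leaving the enumerated reach always exceeds any affinity gain, which is
  what makes the oracle's enumerated set provably sufficient. A
  `c2Mirror` option mirrors the protein, the wells, the anchors *and* the
  noise bit-exactly under a 180° rotation.
* `bruteForceGlobalMinimum()` — an independent exact oracle: with the AIE
  bead fixed it enumerates both chain arms over shells around the spring
  equilibria (`reachPad` 3 Å), prunes by the hard core, and combines the
  two arm lists in best-first order with an exact bound, so the returned
  minimum is the true optimum of the enumerated feasible set. It shares
  no code path with the annealing kernel.

What these fixtures emulate: rugged but smooth-bottomed affinity maps
with a steric core, realistic spring frustration (the planted Lys wells
sit at 12 Å from the anchor, one lattice step off the 13 Å equilibrium),
and exact dimer symmetry. What they do not emulate: the long-range
correlated structure of real electrostatic fields, desolvation, grid
anisotropy, or binding-groove geometry — so passing the oracle and
symmetry tests demonstrates the correctness of the search machinery, not
the biological accuracy of any particular affinity map.

## Numerical choices and degenerate inputs

* Node $(i,j,k)$ (1-based) is centered at
  $\text{origin} + \text{spacing} \cdot (i-1, j-1, k-1)$; DX files use
  the z-fastest value ordering; forbidden nodes serialize as a $10^{30}$
  sentinel because DX has no mask channel.
* A node exactly at an atom's van der Waals radius is allowed (strict
  inequality); a non-bonded bead pair exactly at $d = a$ is allowed
  (the repulsion is zero for $d \ge a$); bonded neighbors are exempt
  from the hard core.
* The placement layer uses exact atom-surface distances
  ($\min_i |x - x_i| - R_i \in [0, \text{thickness})$) when the protein
  is available; with only a mask it falls back to distances to the
  nearest forbidden node, which is coarser by up to one node diagonal.
  An empty layer (including the degenerate thickness-0 request) is an
  error that names the remedy.
* Probe atoms are evaluated by trilinear interpolation; a probe atom
  needing support from a forbidden or out-of-grid node makes that
  orientation infinite, and a node where every orientation is infinite
  is forbidden in the scanned map. The Boltzmann combination over
  rotations is computed as a shifted log-mean-exp, so arbitrarily deep
  minima do not overflow.
* Proposals landing off-grid are evaluated as $+\infty$ and rejected,
  not re-drawn; infinite $\Delta E$ never enters `exp()`.
* Ranking ties (exactly equal final energies) are broken by run index;
  quantile subsets are tie-inclusive.

## Problem sizes used in the shipped checks

The validation suite runs at deliberately small scales chosen so the
exhaustive oracle stays exact and cheap: 15³-node grids at 3 Å spacing,
20 instances × 50 runs for oracle equivalence, 60-run ensembles for the
symmetry checks, 10⁶-step fixed-temperature chains (thinned every 200
proposals after 10% burn-in) for the Boltzmann sampling check on a
256-state enumerable toy system, and 10⁵ draws for the Metropolis
calibration. The production-scale protocol (0.4 Å grids, 150 probe
rotations, 4000 runs) is exposed through `makeReferenceConfigs()` and the
command-line front end, but validating it requires an external protein
structure and is out of scope for the shipped tests.

## Known limitations

* The Debye–Hückel substitute ignores the low-dielectric protein
  interior and desolvation; affinity maps derived from it are
  qualitative.
* Whether the historical probe-scanning pipeline combined rotations by
  Boltzmann weighting or by minimum is not derivable from the protocol
  this package follows; both modes are exposed (`boltzmann` at 300 K is
  the default).
* The chain length is fixed at five beads; bond-angle and torsion terms
  are absent by design.
* The AIE bead is fixed during a run, so the ensemble's pose density is
  conditional on the anchor layer sampling.
* k-medoids is delegated to `cluster::pam()`; only the medoid-based
  summary (not any particular historical clustering) is part of the
  package's contract.
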