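---
title: "Conformer ensemble generation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer ensemble generation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`confsmith` generates low-energy, structurally diverse 3D conformer
ensembles for organic small molecules from connection-table input (SMILES
or SDF). This vignette describes the model and the algorithms, the
parameters that matter and their defaults, the numerical choices, and the
limits of what the test suite can show.

## The problem and the overall strategy

A molecule's biological activity depends on the 3D shapes it can adopt;
most downstream computational methods (docking, pharmacophore searches,
shape screening) consume a discrete *ensemble* of low-energy conformers.
The generator must balance three goals: cover the conformational space
near the global minimum, keep the ensemble compact and structurally
diverse, and run in milliseconds-to-seconds per molecule.

`confsmith` uses two sampling strategies, selected per molecule:

* **Systematic sampling** for typical drug-like molecules. The molecule
  is decomposed into fragments at rotatable bonds, 3D templates are
  generated per fragment, and complete conformers are assembled by
  *torsion driving*: rigid-body alignment of fragment conformers at each
  rotor bond with dihedral angles taken from a knowledge-based torsion
  library.
* **Stochastic sampling** for macrocycles (any SSSR ring with more than
  10 nonaromatic single bonds), where ring closure constrains torsions
  and simple torsion driving cannot reach valid ring geometries. Random
  conformers are generated repeatedly by distance-geometry (DG)
  embedding followed by force-field refinement, until sampling converges.

Energies are MMFF94 throughout (the MMFF94s static variant by default;
for systematic runs the electrostatic term is dropped, which avoids
overweighting intramolecular polar contacts that would be screened by
solvent). Parameter assignment and atom typing are delegated to the
validated RDKit MMFF94 implementation through a bundled Python helper;
the package owns the decomposed-term representation and implements all
energy and gradient evaluation in compiled code. The decomposed
evaluation reproduces the reference engine's total energies to below
1e-12 kcal/mol on charged, aromatic, sulfonamide and donor/acceptor test
molecules (see `test-forcefield.R`), which required three non-obvious
constants: the angle/out-of-plane prefactor is `143.9325*(pi/180)^2`
(not the rounded 0.043844), the cubic-bend coefficient is
-0.006981317 per degree (not -0.007), and the pairwise van der Waals
parameters must be the donor/acceptor-scaled values.

## Preprocessing

Each compound is prepared by: hybridisation perception from element,
charge and incident bond orders; SSSR perception (smallest cycle through
every ring bond, greedily accepted while independent over GF(2) until the
cyclomatic number is reached); Hückel-style aromaticity on 5-7-membered
SSSR rings; stereo perception (input descriptors retained; otherwise
derived from input 3D coordinates by the reader); hydrogen completion
(appended after the heavy atoms, grouped by parent — the index convention
all stereo parities refer to); component labelling by depth-first search;
and per-component topological distance matrices by breadth-first search.

Unconfigured stereogenic double bonds are assigned *trans* with respect
to the bulkiest substituents, judged by Morgan extended-connectivity
values iterated five rounds from the heavy-atom degree with ties broken
by atomic number, charge and hydrogen count (the iteration count is a
design choice: five rounds separate substituents up to a
four-bond-radius neighbourhood, which is enough for steric-bulk ranking
at drug-like sizes). In-ring double bonds in rings of up to seven
members are fixed *cis* with respect to their ring neighbours. Chiral
centres without input configuration are left unspecified and may end up
in either configuration.

**Canonical ordering** (optional, off by default: most users accept
slight output differences between atom orderings of the same molecule
in exchange for skipping the relabelling step) makes the output a pure
function of the labelled graph:
individualisation-refinement search over colour classes (element,
charge, degree, hydrogen count, ring membership, aromaticity, stereo
flags; neighbour multisets with kekulé-independent bond orders),
keeping the lexicographically smallest serialisation, followed by a
deterministic re-kekulisation of aromatic systems (greedy matching with
backtracking in canonical order). With canonicalisation and a fixed
seed, atom-permuted inputs of the same molecule produce byte-identical
output SDF.

## Random conformer generation (DG)

Distance bounds per topological distance class: bonded pairs fixed at
the MMFF94 reference length; geminal pairs at the law-of-cosines
distance; vicinal pairs bounded by the coplanar (cis) and anti-coplanar
(trans) distances — or fixed at one of them across configured double
bonds; remoter pairs bounded below by the covalent-radius sum (Cordero
2008 table) plus a 1.5 Å safety spacing and above by the sum of all
bond lengths. Signed-volume constraints enforce chirality (range
±[0.5, 1000] ų, sign from the configured parity over the
ascending-index neighbour quadruple) and planarity (zero volume for sp2
/aromatic/amide-nitrogen centres with three neighbours, and for
substituent quadruples across double, aromatic and amide bonds).

Embedding minimises the sum of squared bound and volume violations with
L-BFGS from atom positions drawn uniformly in a box of edge
`0.25 × atom count` (0.5 for macrocycles — the larger box reflects the
larger spatial extent of a ring that must close; the non-macrocycle
factor is the package's own choice to keep small molecules compact).
Only heavy atoms and hydrogens bonded to defined stereocentres are
embedded; remaining hydrogens are placed afterwards at ideal geometry
(tetrahedral/trigonal/linear completion at MMFF94 reference X-H
lengths). The embedding is accepted when the mean squared violation per
constraint falls below 2e-3 Ų (≈0.045 Å RMS). This tolerance is loose
enough for bound sets around hypervalent centres (sulfonates,
sulfonamides), whose reference angles are not exactly embeddable, and
far below the signal of a flipped stereocentre (a wrong parity costs at
least 0.25 Å⁶ on its own). Stereo is validated on the raw embedding and
again after refinement; any failure triggers a fresh attempt, up to 10
trials.

Refinement is iterative BFGS minimisation of the MMFF94 energy with a
caller-selected stop rule: for stochastic sampling, energy change ≤
0.001 kcal/mol; for fragment template generation, RMS gradient ≤ 0.5
kcal/mol/Å (templates only need to be reasonable — the driving stage
re-evaluates energies exactly).

## Systematic sampling

**Fragmentation rule** (the package's own documented rule): cut every single,
acyclic bond between two heavy atoms that each carry at least one
further heavy neighbour, skipping bonds at sp centres; amide C–N bonds
are cut but flagged, restricting their torsion angles to the planar
{180°, 0°} pair. Terminal rotors that move only hydrogens are not cut.
This reproduces the ring-systems + linkers + side-chains decomposition
the method is built around.

Fragments are classified: purely aromatic ring systems and rotor-free
chains are **rigid** (one DG conformer); fragments with a non-aromatic
ring are **flexible rings** (stochastic sampling, up to 300 samples with
a 50-cycle convergence check — smaller than the molecule-level defaults
because fragments are small); chains with internal heavy-atom rotors —
counting attachment points as heavy substituents, since caps stand in
for them — are **flexible chains** (one extended conformer; their
torsions are sampled later by driving). Fragment conformers are cached
in a persistent, canonically keyed library populated on miss.

**FCC enumeration.** Fragment conformer combinations are produced
best-first (lazy k-smallest-sums over the per-fragment energy-sorted
lists), so the 100 000-combination cap always retains the lowest-energy
combinations; combinations above the minimum plus 1.5× the energy
window are dropped.

**Torsion driving.** A fragment tree is built by greedily merging the
smallest subtrees across link bonds (deterministic under canonical
order). Every force-field interaction term is statically assigned to
the unique tree node where all its atoms are first jointly present, so
each parametrized interaction is evaluated exactly once per generated
conformer: a node conformer's energy is the sum of its two children's
energies plus the junction terms (rotor-bond stretch, angle/stretch-bend
/out-of-plane terms spanning the junction, torsions at the rotor bond,
and nonbonded pairs whose two atoms lie in different subtrees). This
decomposition is exact — driven-conformer energies agree with a full
recomputation of the merged geometry to ~1e-13 kcal/mol (asserted to
1e-3 in the tests).

Child alignment places the right child's attachment atom along the cap
direction of the left child at the MMFF94 reference length of the cut
bond, then rotates about the axis to the target dihedral, measured over
the highest-connectivity heavy neighbours on either side (IUPAC signed
convention, angles in [0, 360); when a junction atom has no in-subtree
reference neighbour, the cap of another still-open cut bond serves as
the reference point). Torsion angles come from the first matching rule
of the loaded libraries (user libraries take precedence over the
shipped one; a hybridisation-based fallback — staggered 60/180/300 for
sp3–sp3, 0/180 for sp2–sp2, a 60° grid otherwise — guarantees a
nonempty list). Angles equivalent under two- or threefold rotational
symmetry of either side (phenyl, nitro, trifluoromethyl, tert-butyl and
the like, detected from automorphism orbits of the side subgraph with
geometric compatibility conditions rather than a fixed pattern table)
are collapsed. Optional tolerance-range sampling adds each angle's
first-tolerance endpoints.

The driving loop processes FCCs in ascending combination energy, prunes
candidates above the adaptive window at every node (pool cap 10 000),
and exits early when the FCC energy exceeds the energy of the FCC that
produced the best conformer so far plus the window, or when the working
set reaches the pool cap.

## Stochastic sampling

Random conformers are generated until 2000 samples, a wall-clock
budget, or convergence: every 100 cycles, energy-duplicates (pairwise
within 0.01 kcal/mol; lowest survivor) are removed, and sampling stops
when the unique count did not grow since the previous check. Failed
generation attempts count as cycles (the convergence statistics are
about sampling effort, not successes). Members above the adaptive
energy window (20 kcal/mol default for stochastic runs) are discarded
at the end. Energy-only duplicate detection can merge distinct
isoenergetic conformers (e.g. enantiomeric ring forms); the final
geometric diversity selection makes this harmless for the output.

## Output compilation

Candidates are ranked by increasing energy and picked greedily: a
conformer enters the ensemble only if its symmetry-aware heavy-atom
RMSD to every already-selected conformer is at least the threshold
(default 0.5 Å). RMSD minimisation uses the closed-form Kabsch
superposition (proper rotations only) minimised over all topological
symmetry mappings — automorphisms of the heavy-atom graph preserving
element, charge, hydrogen count and bond order, enumerated by
colour-refinement-guided backtracking up to a hard cap of 131 072
(if the cap is hit, the diversity guarantee is relaxed and flagged).
Selection stops at the ensemble size cap or outside the energy window
(default 15 kcal/mol for systematic runs). An input 3D structure, when
inclusion is requested, is inserted as the first candidate before
picking, then subject to the same window and diversity rules; it can
therefore occupy a slot a lower-energy generated conformer would have
taken — the choice favours reproducing the input geometry. Note that
RMSD under different optimal mappings is not a metric; no triangle
inequality is implied or used. Equal energies keep generation order
(stable sort).

Multi-component compounds (salts, mixtures) get one ensemble per
component; compound conformers pair the i-th conformers of each
component, translated apart along x with a 5 Å bounding-box gap. This
naive placement is a documented stand-in for a real packing algorithm
and makes no claim about inter-component geometry.

## Parameters at a glance

| Parameter | Default | Unit | Where |
|---|---|---|---|
| Energy window | 15 systematic / 20 stochastic | kcal/mol | ensemble membership |
| RMSD threshold | 0.5 | Å | output diversity |
| Max ensemble size | 100 | conformers | output |
| Stochastic sample cap | 2000 | cycles | sampling loop |
| Convergence check period | 100 | cycles | sampling loop |
| Duplicate window | 0.01 | kcal/mol | duplicate removal |
| DG trials | 10 | attempts | random generation |
| FCC cap / safety factor | 100 000 / 1.5 | — | FCC enumeration |
| Node pool cap | 10 000 | conformers | torsion driving |
| Symmetry mapping cap | 131 072 | mappings | RMSD |

## What the synthetic fixtures do and do not show

The generator is exercised on synthetic molecule sets built from
drug-like ring cores, linkers and substituent caps (≤ 8 rotors,
MMFF94-covered elements), saturated 12-24-membered macrocycles, salts,
and stereo-defined molecules. These cover the method's control flow —
fragmentation shapes, symmetric sides, amides/esters, charged groups,
chirality and double-bond geometry, multi-component input — but they are
small (mostly 10–25 heavy atoms), conformationally simple, and contain
no tautomeric ambiguity, no crowded stereocentre clusters, and no
experimental reference geometries. Passing tests therefore demonstrate
internal consistency (exact incremental energies, preserved stereo,
satisfied ensemble invariants, reproducibility) — not accuracy against
crystallographic bioactive conformations, which would require external
benchmark datasets. The acceptance script runs 50-molecule batches and
20-molecule driving checks; these sizes are the package's reporting
choice and can be raised freely.

## Known limitations

* MMFF94 coverage limits the element/valence space; uncovered molecules
  fail cleanly at parametrization.
* The torsion library is a compact hybridisation-plus-functional-group
  set, not a statistically derived one; users can drop in richer
  libraries via `--torsion-lib` (first match wins).
* Amide nitrogens are always treated as planar; strongly pyramidal
  amides are not represented.
* The stochastic path does not use torsion mutation or annealing moves;
  very large macrocycles may need more than the default 2000 samples.
* Multi-component placement is geometric separation only.
* Symmetry reduction of torsion angles uses graph orbits plus
  conservative geometric conditions; rare non-planar symmetric sides
  fall back to the unreduced angle list (costing duplicates, never
  coverage).
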