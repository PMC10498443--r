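# confsmith

Conformer ensemble generation for drug-like small molecules and
macrocycles, in R.

Most structure-based and ligand-based drug-discovery methods — docking,
pharmacophore searching, shape screening — consume a discrete set of
low-energy 3D conformers per molecule. `confsmith` produces such
ensembles from plain connection tables (SMILES or SDF): structurally
diverse, energy-ordered, stereo-faithful, written as multi-conformer SDF.

## The method in brief

Two sampling strategies, selected automatically per molecule:

* **Systematic sampling** (drug-like molecules): the molecule is cut at
  rotatable bonds into fragments; fragment 3D templates are generated by
  distance geometry (and cached in a persistent library); fragment
  conformer combinations (FCCs) are enumerated best-first by combined
  energy $E_{comb} = \sum_i E_i$; complete conformers are assembled over
  a fragment tree by torsion driving — rigid-body alignment of child
  conformers at each rotor bond for every library dihedral angle
  $\Theta$, with the incremental energy

  $$E_{A\text{–}B}(\Theta) = E_A + E_B + E_{BS} + E_T(\Theta) + E_C(\Theta) + E_{VdW}(\Theta)$$

  where $E_A, E_B$ are the (cached) child energies, $E_{BS}$ the rotor
  bond stretch, $E_T$ the torsions at the rotor bond and $E_C, E_{VdW}$
  the electrostatic and van der Waals interactions between the two
  substructures. Every parametrized MMFF94 interaction is evaluated once
  per generated conformer; the decomposition is exact.

* **Stochastic sampling** (macrocycles: any SSSR ring with more than 10
  nonaromatic single bonds): repeated random-conformer generation by
  distance-geometry embedding (pairwise distance bounds + signed-volume
  chirality/planarity constraints) and BFGS refinement of the MMFF94
  energy, with energy-window filtering and convergence detection.

Output ensembles are compiled by greedy energy-ordered selection under a
symmetry-aware heavy-atom RMSD diversity threshold (Kabsch superposition
minimised over all graph automorphisms, capped at 131 072 mappings).

MMFF94(s) atom typing and parameters come from the validated RDKit
implementation via a bundled Python helper; all energy/gradient
evaluation, embedding, torsion driving and selection machinery is
implemented in the package (R + C++). See the vignette
(`vignettes/conformer-generation.Rmd`) for the full account.

## Worked example

```r
library(confsmith)

mol <- parse_smiles("CC(=O)Nc1ccc(O)cc1", names = "paracetamol")[[1]]
res <- generate_conformers(mol, generation_settings(seed = 7))

res$report$status
#> [1] "ok"
res$ensemble
#> <conformer_ensemble> paracetamol: 3 conformer(s), E 73.747 .. 83.738 kcal/mol
sapply(res$ensemble$conformers, function(c_) round(c_$energy, 3))
#> [1] 73.747 75.203 83.738

write_ensemble(res$ensemble, "paracetamol.sdf")
best_rmsd(res$ensemble, res$ensemble$conformers[[1]]$coords)
#> [1] 6.285479e-16
```

The three conformers are the trans-amide rotamer family of paracetamol:
energies are MMFF94s totals (kcal/mol; absolute values are force-field
internal energies, only differences are meaningful — the 1.5 kcal/mol
gap separates the two phenol O–H orientations, the 10 kcal/mol gap the
cis-amide form). Every pair of output conformers is at least 0.5 Å apart
in symmetry-aware heavy-atom RMSD, and the `best_rmsd` of a reference
drawn from the ensemble itself is zero to machine precision.

Command-line use (after install, from `inst/exec/`):

```sh
confsmith -i molecules.smi -o ensembles.sdf -m auto -e 15 -r 0.5 -n 100 --seed 1
confsmith-bench --ensembles ensembles.sdf --references refs.sdf --thresholds 0.5,1.0,2.0
```

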