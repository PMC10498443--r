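Package: confsmith
Title: Conformer Ensemble Generation for Drug-Like Molecules and Macrocycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates low-energy, structurally diverse conformer ensembles for
    small organic molecules. Drug-like molecules are sampled systematically by
    fragment decomposition and knowledge-based torsion driving with incremental
    MMFF94 energy evaluation; macrocycles are sampled stochastically through
    distance-geometry embedding followed by force-field refinement. Includes a
    symmetry-aware heavy-atom RMSD toolkit (Kabsch superposition over graph
    automorphisms) for ensemble diversity selection and benchmarking against
    reference structures, plus multi-conformer SDF input/output. MMFF94
    parameters are obtained from the validated RDKit implementation through a
    bundled Python helper; all energy evaluation, embedding, torsion driving and
    selection machinery is implemented in R and C++.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: Python (>= 3.8) with the rdkit package importable
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
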