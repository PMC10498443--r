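# Shared helpers: cached parsed molecules and an independent RDKit MMFF94
# total-energy oracle (used to cross-check the package's own decomposed
# evaluation; the oracle never replaces it).

.mol_cache <- new.env(parent = emptyenv())

fix_mol <- function(smiles, canonical = FALSE) {
  key <- paste0(smiles, "|", canonical)
  if (!exists(key, envir = .mol_cache)) {
    assign(key, preprocess(parse_smiles(smiles)[[1]], canonical = canonical),
           envir = .mol_cache)
  }
  get(key, envir = .mol_cache)
}

fix_param <- function(smiles, variant = "MMFF94s", no_estat = FALSE) {
  key <- paste0("P|", smiles, "|", variant, "|", no_estat)
  if (!exists(key, envir = .mol_cache)) {
    assign(key, parametrize(fix_mol(smiles), variant = variant,
                            no_estat = no_estat), envir = .mol_cache)
  }
  get(key, envir = .mol_cache)
}

# Reference MMFF94 total energy computed by RDKit on given coordinates.
rdkit_mmff_total <- function(mol, coords, variant = "MMFF94s") {
  mb <- write_molblock(mol, coords)
  script <- '
import sys, json
from rdkit import Chem
from rdkit.Chem import ChemicalForceFields  # noqa
from rdkit.Chem import rdForceFieldHelpers as FF
from rdkit.Geometry import Point3D
req = json.load(open(sys.argv[1]))
mol = Chem.MolFromMolBlock(req["molblock"], removeHs=False)
conf = mol.GetConformer()
for k, p in enumerate(req["coords"]):
    conf.SetAtomPosition(k, Point3D(*p))
props = FF.MMFFGetMoleculeProperties(mol, mmffVariant=req["variant"])
ff = FF.MMFFGetMoleculeForceField(mol, props)
print(ff.CalcEnergy())
'
  sf <- tempfile(fileext = ".py")
  jf <- tempfile(fileext = ".json")
  on.exit(unlink(c(sf, jf)), add = TRUE)
  writeLines(script, sf)
  jsonlite::write_json(list(molblock = mb,
                            coords = apply(coords, 1, as.list,
                                           simplify = FALSE),
                            variant = variant),
                       jf, auto_unbox = TRUE, digits = NA)
  out <- system2(find_python(), c(shQuote(sf), shQuote(jf)), stdout = TRUE)
  as.numeric(out[length(out)])
}

# random connected molecular-like graph for shortest-path oracles
random_connected_graph <- function(n, extra_edges = 2L) {
  stopifnot(n >= 2)
  edges <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1L, 1L), 1L))
  for (t in seq_len(extra_edges)) {
    pair <- sort(sample.int(n, 2L))
    edges <- rbind(edges, pair)
  }
  edges <- unique(t(apply(edges, 1, sort)))
  edges
}

floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    d[edges[r, 1], edges[r, 2]] <- 1
    d[edges[r, 2], edges[r, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

graph_to_mol <- function(n, edges) {
  mol_graph(data.frame(element = rep("C", n), charge = 0L, nH = 0L,
                       aromatic = FALSE),
            data.frame(i = edges[, 1], j = edges[, 2], order = 1L,
                       aromatic = FALSE))
}

run_systematic <- function(smiles, seed = 1L) {
  m <- fix_mol(smiles)
  libs <- list(load_torsion_library())
  p <- parametrize(m, no_estat = TRUE,
                   torsion_smarts = confsmith:::torsion_library_smarts(libs))
  fr <- fragment_molecule(m)
  fp <- prepare_systematic(m, fr)
  set.seed(seed)
  res <- systematic_sample(m, p, fp, fr, libs)
  list(mol = m, param = p, frag = fr, res = res)
}

# brute-force automorphism count oracle (label- and bond-order-aware)
brute_force_automorphisms <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  nh <- length(heavy)
  adjm <- matrix(0L, nh, nh)
  hmap <- integer(n_atoms(mol)); hmap[heavy] <- seq_len(nh)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- hmap[mol$bonds$i[r]]; j <- hmap[mol$bonds$j[r]]
    if (i == 0 || j == 0) next
    o <- if (isTRUE(mol$bonds$aromatic[r])) 9L else mol$bonds$order[r]
    adjm[i, j] <- o; adjm[j, i] <- o
  }
  el <- mol$atoms$element[heavy]
  adjf <- confsmith:::adjacency(mol)
  nh_count <- vapply(heavy, function(a) {
    sum(mol$atoms$element[adjf[[a]]] == "H") }, 0L)
  count <- 0L
  perms <- gtools_permutations(nh)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (any(el[p] != el) || any(nh_count[p] != nh_count)) next
    if (identical(adjm[p, p], adjm)) count <- count + 1L
  }
  count
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

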