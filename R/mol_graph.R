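# MoleculeGraph: an annotated connection table and the perception steps
# (hybridisation, SSSR, aromaticity, stereo, hydrogen completion,
# canonical ordering, component labelling, topological distances) that
# prepare an input compound for conformer generation.

#' Construct a molecule graph
#'
#' The central container of the package: an annotated connection table with
#' optional 3D coordinates and stereo descriptors. Atom indices are 1-based
#' and stable; hydrogens added by [add_missing_hydrogens()] are appended
#' after the heavy atoms, grouped by parent atom.
#'
#' @param atoms data.frame with columns `element`, `charge`, `nH`
#'   (implicit hydrogens still to be materialised), `aromatic`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3;
#'   kekulised), `aromatic`.
#' @param name molecule name.
#' @param coords optional N x 3 matrix of input coordinates (Angstrom).
#' @param stereo_atoms data.frame of defined tetrahedral centres: `center`,
#'   `n1`..`n4` (neighbour indices in ascending order), `parity` (sign of
#'   the signed volume spanned by the ordered neighbours), `cip`.
#' @param stereo_bonds data.frame of defined double-bond configurations:
#'   `a`, `b` (bond atoms), `ref_a`, `ref_b` (reference substituents),
#'   `config` ("cis" = references on the same side), `specified`.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds, name = "", coords = NULL,
                      stereo_atoms = NULL, stereo_bonds = NULL) {
  atoms$element <- as.character(atoms$element)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$nH)) atoms$nH <- NA_integer_
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms$hyb <- if (is.null(atoms$hyb)) NA_character_ else atoms$hyb
  atoms$comp <- if (is.null(atoms$comp)) NA_integer_ else atoms$comp
  if (is.null(atoms$cip)) atoms$cip <- NA_character_
  if (nrow(bonds)) {
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    bonds$in_ring <- if (is.null(bonds$in_ring)) NA else bonds$in_ring
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        aromatic = logical(), in_ring = logical())
  }
  if (is.null(stereo_atoms)) {
    stereo_atoms <- data.frame(center = integer(), n1 = integer(),
                               n2 = integer(), n3 = integer(), n4 = integer(),
                               parity = integer(), cip = character())
  }
  if (is.null(stereo_bonds)) {
    stereo_bonds <- data.frame(a = integer(), b = integer(),
                               ref_a = integer(), ref_b = integer(),
                               config = character(), specified = logical())
  }
  structure(list(name = name, atoms = atoms, bonds = bonds, coords = coords,
                 stereo_atoms = stereo_atoms, stereo_bonds = stereo_bonds,
                 sssr = NULL),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, %d component(s)%s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds),
              if (all(is.na(x$atoms$comp))) 1L else max(x$atoms$comp),
              if (is.null(x$coords)) "" else ", 3D"))
  invisible(x)
}

#' Number of atoms in a molecule graph
#' @param mol a `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

is_hydrogen <- function(mol) mol$atoms$element == "H"

#' Adjacency list of a molecule graph
#' @keywords internal
adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

bond_lookup <- function(mol) {
  # environment mapping "i-j" (i<j) -> bond row
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      k <- bond_key(mol$bonds$i[r], mol$bonds$j[r])
      assign(k, r, envir = env)
    }
  }
  env
}

bond_key <- function(i, j) paste0(min(i, j), "-", max(i, j))

find_bond <- function(mol, i, j) {
  hit <- which((mol$bonds$i == i & mol$bonds$j == j) |
               (mol$bonds$i == j & mol$bonds$j == i))
  if (length(hit)) hit[1] else NA_integer_
}

# ---------------------------------------------------------------------------
# Component perception (depth-first search)

#' Label connected components of a compound
#'
#' Atoms reachable from each other via bond paths form one component
#' (a molecule in the chemical sense); salts and mixtures have several.
#'
#' @param mol a `mol_graph`.
#' @return The graph with `atoms$comp` filled in.
#' @export
perceive_components <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      for (w in adj[[v]]) if (is.na(comp[w])) stack <- c(stack, w)
    }
  }
  mol$atoms$comp <- comp
  mol
}

#' Number of components (after perception)
#' @export
n_components <- function(mol) {
  if (all(is.na(mol$atoms$comp))) mol <- perceive_components(mol)
  max(mol$atoms$comp)
}

#' Extract one component as a standalone molecule graph
#'
#' @param mol compound graph with components perceived.
#' @param k component id.
#' @return `mol_graph` for the component; attribute `parent_index` maps
#'   component atom indices back to the compound.
#' @export
get_component <- function(mol, k) {
  if (all(is.na(mol$atoms$comp))) mol <- perceive_components(mol)
  keep <- which(mol$atoms$comp == k)
  subset_mol(mol, keep)
}

# Extract induced subgraph on `keep` (index vector), remapping all
# annotations. Used for components and fragments.
subset_mol <- function(mol, keep) {
  map <- match(seq_len(n_atoms(mol)), keep)  # old -> new (NA if dropped)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  brows <- which(!is.na(map[mol$bonds$i]) & !is.na(map[mol$bonds$j]))
  bonds <- mol$bonds[brows, , drop = FALSE]
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  rownames(bonds) <- NULL
  sa <- mol$stereo_atoms
  sa_keep <- !is.na(map[sa$center]) & !is.na(map[sa$n1]) & !is.na(map[sa$n2]) &
             !is.na(map[sa$n3]) & !is.na(map[sa$n4])
  sa <- sa[sa_keep, , drop = FALSE]
  if (nrow(sa)) {
    for (col in c("center", "n1", "n2", "n3", "n4")) sa[[col]] <- map[sa[[col]]]
    sa <- resort_stereo_atoms(sa)
  }
  sb <- mol$stereo_bonds
  sb_keep <- !is.na(map[sb$a]) & !is.na(map[sb$b]) &
             !is.na(map[sb$ref_a]) & !is.na(map[sb$ref_b])
  sb <- sb[sb_keep, , drop = FALSE]
  if (nrow(sb)) for (col in c("a", "b", "ref_a", "ref_b")) sb[[col]] <- map[sb[[col]]]
  rownames(sb) <- NULL
  out <- mol_graph(atoms, bonds, name = mol$name,
                   coords = if (is.null(mol$coords)) NULL
                            else mol$coords[keep, , drop = FALSE],
                   stereo_atoms = sa, stereo_bonds = sb)
  attr(out, "parent_index") <- keep
  out
}

# Re-sort stereo neighbour columns ascending, adjusting parity by the sign
# of the sorting permutation.
resort_stereo_atoms <- function(sa) {
  for (r in seq_len(nrow(sa))) {
    nb <- c(sa$n1[r], sa$n2[r], sa$n3[r], sa$n4[r])
    ord <- order(nb)
    sa$parity[r] <- sa$parity[r] * perm_sign(ord)
    nb <- nb[ord]
    sa$n1[r] <- nb[1]; sa$n2[r] <- nb[2]; sa$n3[r] <- nb[3]; sa$n4[r] <- nb[4]
  }
  rownames(sa) <- NULL
  sa
}

perm_sign <- function(p) {
  # sign of a permutation given as a vector of positions
  visited <- logical(length(p))
  s <- 1L
  for (i in seq_along(p)) {
    if (visited[i]) next
    j <- i; len <- 0L
    while (!visited[j]) { visited[j] <- TRUE; j <- p[j]; len <- len + 1L }
    if (len %% 2L == 0L) s <- -s
  }
  s
}

# ---------------------------------------------------------------------------
# Topological distances (breadth-first search)

#' Topological distance matrix of a connected component
#'
#' Shortest bond-path lengths between all atom pairs, via breadth-first
#' search from every atom. Needed for distance-geometry bounds and for the
#' MMFF94 nonbonded interaction gating (pairs closer than three bonds are
#' excluded; 1-4 electrostatics are scaled).
#'
#' @param mol connected `mol_graph`.
#' @return Integer matrix `TD` with `TD[i, j]` = number of bonds on the
#'   shortest path.
#' @export
topological_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  td <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    td[s, ] <- dist
  }
  if (anyNA(td)) stop("topological_distances requires a connected component")
  td
}

# ---------------------------------------------------------------------------
# SSSR, hybridisation, aromaticity

#' Smallest set of smallest rings
#'
#' Minimal cycle basis of the molecular graph: for every ring bond the
#' smallest cycle through it is determined (BFS on the graph with that bond
#' removed); candidate rings are then accepted in order of increasing size
#' (ties by lexicographic atom set) while linearly independent over GF(2)
#' on bond space, until the cyclomatic number is reached.
#'
#' @param mol a `mol_graph`.
#' @return List of integer vectors (ring atom indices, in ring order).
#' @export
perceive_sssr <- function(mol) {
  n <- n_atoms(mol)
  m <- nrow(mol$bonds)
  if (all(is.na(mol$atoms$comp))) mol <- perceive_components(mol)
  ncomp <- max(mol$atoms$comp, 0L)
  n_rings <- m - n + ncomp
  if (n_rings <= 0) return(list())
  adj <- adjacency(mol)
  candidates <- list()
  for (r in seq_len(m)) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    # shortest path i -> j avoiding bond r
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    queue <- i
    while (length(queue) && is.na(dist[j])) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == i && w == j) || (v == j && w == i)) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[j])) next  # bridge bond, not in a ring
    path <- j
    while (path[length(path)] != i) path <- c(path, prev[path[length(path)]])
    candidates[[length(candidates) + 1L]] <- rev(path)
  }
  if (!length(candidates)) return(list())
  sizes <- vapply(candidates, length, 1L)
  keys <- vapply(candidates, function(p) paste(sort(p), collapse = ","), "")
  ord <- order(sizes, keys)
  candidates <- candidates[ord]
  keys <- keys[ord]
  candidates <- candidates[!duplicated(keys)]
  # greedy GF(2)-independent selection on bond incidence vectors
  basis <- matrix(FALSE, 0, m)
  rings <- list()
  for (ring in candidates) {
    if (length(rings) >= n_rings) break
    vec <- rep(FALSE, m)
    nr <- length(ring)
    for (t in seq_len(nr)) {
      a <- ring[t]; b <- ring[if (t == nr) 1L else t + 1L]
      vec[find_bond(mol, a, b)] <- TRUE
    }
    red <- vec
    if (nrow(basis)) {
      for (br in seq_len(nrow(basis))) {
        pivot <- which(basis[br, ])[1]
        if (red[pivot]) red <- xor(red, basis[br, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

#' Perceive hybridisation, rings and aromaticity
#'
#' Hybridisation is derived from the element, formal charge and incident
#' bond orders (triple bond or two cumulated double bonds: sp; any double
#' or aromatic bond: sp2; otherwise sp3 for main-group centres). The SSSR
#' is perceived and atoms/bonds flagged as ring members; rings whose pi
#' electron count satisfies the 4n+2 rule with every member sp2-capable are
#' marked aromatic.
#'
#' @param mol a `mol_graph`.
#' @return The annotated graph (fields `hyb`, `aromatic`, `in_ring`,
#'   `sssr` filled).
#' @export
perceive_atom_properties <- function(mol) {
  check_valences(mol)
  mol <- perceive_components(mol)
  n <- n_atoms(mol)
  el <- mol$atoms$element
  nb_orders <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[r]; j <- mol$bonds$j[r]; o <- mol$bonds$order[r]
      nb_orders[[i]] <- c(nb_orders[[i]], o)
      nb_orders[[j]] <- c(nb_orders[[j]], o)
    }
  }
  hyb <- character(n)
  for (a in seq_len(n)) {
    os <- nb_orders[[a]]
    if (el[a] %in% c("H", "F", "Cl", "Br", "I") || !length(os)) {
      hyb[a] <- "other"
    } else if (any(os == 3L) || sum(os == 2L) >= 2L) {
      hyb[a] <- "sp"
    } else if (any(os == 2L) || isTRUE(mol$atoms$aromatic[a])) {
      hyb[a] <- "sp2"
    } else if (el[a] %in% c("C", "N", "O", "S", "P", "B", "Si", "Se")) {
      hyb[a] <- "sp3"
    } else {
      hyb[a] <- "other"
    }
  }
  mol$atoms$hyb <- hyb
  rings <- perceive_sssr(mol)
  mol$sssr <- rings
  in_ring_atom <- rep(FALSE, n)
  in_ring_bond <- rep(FALSE, nrow(mol$bonds))
  for (ring in rings) {
    in_ring_atom[ring] <- TRUE
    nr <- length(ring)
    for (t in seq_len(nr)) {
      in_ring_bond[find_bond(mol, ring[t], ring[if (t == nr) 1L else t + 1L])] <- TRUE
    }
  }
  mol$atoms$in_ring <- in_ring_atom
  mol$bonds$in_ring <- in_ring_bond
  mol <- perceive_aromaticity(mol)
  # aromatic members are sp2 regardless of kekule assignment
  mol$atoms$hyb[mol$atoms$aromatic & mol$atoms$hyb == "sp3"] <- "sp2"
  # amide nitrogens are planar (delocalised lone pair)
  adj2 <- adjacency(mol)
  for (a in seq_len(n)) {
    if (el[a] != "N" || mol$atoms$hyb[a] != "sp3") next
    for (c_ in adj2[[a]]) {
      if (mol$atoms$element[c_] != "C") next
      for (o in adj2[[c_]]) {
        b <- find_bond(mol, c_, o)
        if (mol$atoms$element[o] == "O" && mol$bonds$order[b] == 2L) {
          mol$atoms$hyb[a] <- "sp2"
        }
      }
    }
  }
  mol
}

# Hueckel-style perception on SSSR rings; input aromatic flags are kept.
perceive_aromaticity <- function(mol) {
  rings <- mol$sssr
  if (is.null(rings)) return(mol)
  n <- n_atoms(mol)
  el <- mol$atoms$element
  dbl_partner <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[r] == 2L) {
        i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
        dbl_partner[[i]] <- c(dbl_partner[[i]], j)
        dbl_partner[[j]] <- c(dbl_partner[[j]], i)
      }
    }
  }
  for (ring in rings) {
    if (length(ring) < 5 || length(ring) > 7) next
    pi_e <- 0L
    ok <- TRUE
    for (a in ring) {
      dp <- dbl_partner[[a]]
      if (length(dp) && any(dp %in% ring)) {
        pi_e <- pi_e + 1L
      } else if (length(dp)) {
        pi_e <- pi_e + 0L      # exocyclic double bond
      } else if (el[a] %in% c("N", "O", "S", "P", "Se")) {
        pi_e <- pi_e + 2L      # lone-pair donor
      } else if (el[a] == "C" && mol$atoms$charge[a] == -1L) {
        pi_e <- pi_e + 2L
      } else if (el[a] == "C" && mol$atoms$charge[a] == 1L) {
        pi_e <- pi_e + 0L
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok && pi_e %% 4L == 2L) {
      mol$atoms$aromatic[ring] <- TRUE
      nr <- length(ring)
      for (t in seq_len(nr)) {
        b <- find_bond(mol, ring[t], ring[if (t == nr) 1L else t + 1L])
        mol$bonds$aromatic[b] <- TRUE
      }
    }
  }
  mol
}

STD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                 S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

effective_valence <- function(element, charge) {
  v <- STD_VALENCE[element]
  if (is.na(v)) return(NA_real_)
  if (element %in% c("N", "O", "P", "S", "Se")) v <- v + charge
  if (element %in% c("C", "Si")) v <- v - abs(charge)
  if (element %in% c("F", "Cl", "Br", "I", "H") && charge != 0) v <- 0
  if (element == "B") v <- v + charge
  max(v, 0)
}

check_valences <- function(mol) {
  n <- n_atoms(mol)
  bsum <- rep(0L, n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[r]
      bsum[mol$bonds$i[r]] <- bsum[mol$bonds$i[r]] + o
      bsum[mol$bonds$j[r]] <- bsum[mol$bonds$j[r]] + o
    }
  }
  for (a in seq_len(n)) {
    el <- mol$atoms$element[a]
    if (!el %in% names(STD_VALENCE)) next
    ev <- effective_valence(el, mol$atoms$charge[a])
    lim <- ev
    if (el == "S") lim <- 6
    if (el == "P") lim <- 5
    if (el == "N" && mol$atoms$charge[a] == 0 && bsum[a] > 3 ||
        el == "C" && mol$atoms$charge[a] == 0 && bsum[a] > 4 ||
        bsum[a] > max(lim, 0) && !el %in% c("S", "P")) {
      stop(sprintf("impossible valence at atom %d (%s, %d bonds)",
                   a, el, bsum[a]), call. = FALSE)
    }
  }
  invisible(mol)
}

# ---------------------------------------------------------------------------
# Hydrogen completion

#' Convert implicit hydrogens to explicit atoms
#'
#' Appends hydrogen atoms after the heavy atoms, grouped by parent atom in
#' index order (the convention all stereo parities in the package refer
#' to). The number of hydrogens per atom is taken from the reader when
#' available, otherwise derived from the element's standard valence state
#' and formal charge. Protonation states are never altered; only implicit
#' hydrogens are materialised.
#'
#' @param mol a `mol_graph`.
#' @return Hydrogen-complete graph.
#' @export
add_missing_hydrogens <- function(mol) {
  n <- n_atoms(mol)
  bsum <- rep(0, n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[r]
      bsum[mol$bonds$i[r]] <- bsum[mol$bonds$i[r]] + o
      bsum[mol$bonds$j[r]] <- bsum[mol$bonds$j[r]] + o
    }
  }
  nh <- mol$atoms$nH
  for (a in seq_len(n)) {
    if (!is.na(nh[a])) next
    if (mol$atoms$element[a] == "H") { nh[a] <- 0L; next }
    ev <- effective_valence(mol$atoms$element[a], mol$atoms$charge[a])
    nh[a] <- if (is.na(ev)) 0L else as.integer(max(0, round(ev - bsum[a])))
  }
  total <- sum(nh)
  if (total == 0L) { mol$atoms$nH <- 0L; return(mol) }
  hat <- data.frame(element = rep("H", total), charge = 0L, nH = 0L,
                    aromatic = FALSE, hyb = "other", comp = NA_integer_,
                    cip = NA_character_)
  newb <- data.frame(i = integer(total), j = integer(total),
                     order = 1L, aromatic = FALSE, in_ring = FALSE)
  idx <- n
  r <- 0L
  for (a in seq_len(n)) {
    if (nh[a] == 0L) next
    for (t in seq_len(nh[a])) {
      idx <- idx + 1L
      r <- r + 1L
      newb$i[r] <- a
      newb$j[r] <- idx
    }
  }
  mol$atoms$nH <- 0L
  mol$atoms <- rbind(mol$atoms[, c("element", "charge", "nH", "aromatic",
                                   "hyb", "comp", "cip")], hat)
  rownames(mol$atoms) <- NULL
  mol$bonds <- rbind(mol$bonds, newb)
  rownames(mol$bonds) <- NULL
  if (!is.null(mol$coords)) {
    mol$coords <- rbind(mol$coords, matrix(NA_real_, total, 3))
  }
  mol
}

# ---------------------------------------------------------------------------
# Morgan connectivity values and stereo assignment

#' Iterated Morgan connectivity values
#'
#' Extended-connectivity sums iterated for a fixed number of rounds from
#' the initial heavy-atom degree; used to estimate the steric bulk of
#' substituents when assigning default double-bond geometry. Ties are
#' broken by atomic number, formal charge and hydrogen count.
#'
#' @param mol a `mol_graph`.
#' @param rounds number of extended-connectivity iterations.
#' @return Numeric vector of connectivity values (higher = bulkier).
#' @export
morgan_connectivity <- function(mol, rounds = 5L) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  heavy <- !is_hydrogen(mol)
  cv <- vapply(seq_len(n), function(a) sum(heavy[adj[[a]]]), 0)
  for (it in seq_len(rounds)) {
    cv <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      sum(cv[nb[heavy[nb]]])
    }, 0)
  }
  z <- atomic_number(mol$atoms$element)
  nh_tot <- vapply(seq_len(n), function(a) {
    sum(!heavy[adj[[a]]]) + ifelse(is.na(mol$atoms$nH[a]), 0L, mol$atoms$nH[a])
  }, 0)
  cv + z / 1e3 + (mol$atoms$charge + 10) / 1e6 + nh_tot / 1e8
}

ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

atomic_number <- function(el) {
  z <- ATOMIC_NUMBERS[el]
  z[is.na(z)] <- 0
  unname(z)
}

#' Assign stereo descriptors
#'
#' Input descriptors (from SMILES or from 3D/wedge information resolved by
#' the reader) are retained. Stereogenic double bonds that remain
#' unconfigured are assigned a trans arrangement of the sterically most
#' bulky substituent on either side, judged by iterated Morgan connectivity
#' values; in-ring double bonds in rings of up to seven members are fixed
#' cis with respect to their ring neighbours. Chiral atoms without input
#' configuration are left unspecified.
#'
#' @param mol a perceived, hydrogen-complete `mol_graph`.
#' @return Graph with `stereo_bonds` completed.
#' @export
assign_stereo <- function(mol) {
  adj <- adjacency(mol)
  heavy <- !is_hydrogen(mol)
  cv <- morgan_connectivity(mol)
  configured <- character(0)
  if (nrow(mol$stereo_bonds)) {
    configured <- vapply(seq_len(nrow(mol$stereo_bonds)), function(r) {
      bond_key(mol$stereo_bonds$a[r], mol$stereo_bonds$b[r])
    }, "")
  }
  for (r in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[r] != 2L || isTRUE(mol$bonds$aromatic[r])) next
    a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
    if (bond_key(a, b) %in% configured) next
    if (mol$atoms$element[a] == "O" || mol$atoms$element[b] == "O") next
    sub_a <- setdiff(adj[[a]], b)
    sub_b <- setdiff(adj[[b]], a)
    if (!length(sub_a) || !length(sub_b)) next
    if (length(sub_a) > 2 || length(sub_b) > 2) next  # hypervalent, skip
    in_small_ring <- FALSE
    if (isTRUE(mol$bonds$in_ring[r]) && !is.null(mol$sssr)) {
      for (ring in mol$sssr) {
        if (a %in% ring && b %in% ring && length(ring) <= 7) {
          ra <- intersect(sub_a, ring)
          rb <- intersect(sub_b, ring)
          if (length(ra) && length(rb)) {
            mol$stereo_bonds <- rbind(mol$stereo_bonds, data.frame(
              a = a, b = b, ref_a = ra[1], ref_b = rb[1],
              config = "cis", specified = FALSE))
            in_small_ring <- TRUE
          }
          break
        }
      }
    }
    if (in_small_ring) next
    # stereogenic only if the substituents on each side are distinguishable
    distinct_a <- length(sub_a) == 1 || abs(cv[sub_a[1]] - cv[sub_a[2]]) > 1e-9
    distinct_b <- length(sub_b) == 1 || abs(cv[sub_b[1]] - cv[sub_b[2]]) > 1e-9
    if (!distinct_a || !distinct_b) next
    ref_a <- sub_a[which.max(cv[sub_a])]
    ref_b <- sub_b[which.max(cv[sub_b])]
    mol$stereo_bonds <- rbind(mol$stereo_bonds, data.frame(
      a = a, b = b, ref_a = ref_a, ref_b = ref_b,
      config = "trans", specified = FALSE))
  }
  rownames(mol$stereo_bonds) <- NULL
  mol
}

# ---------------------------------------------------------------------------
# Canonical ordering

#' Canonically reorder the atoms of a molecule graph
#'
#' Deterministic canonical labelling by iterative partition refinement:
#' atoms start with an invariant built from element, charge, degree, total
#' hydrogen count, ring membership, aromaticity and stereo flags, then
#' refine on sorted neighbour-rank multisets until stable. Atoms are
#' reordered by final rank (heavy atoms first, hydrogens regrouped after
#' their parents), so the output order is a pure function of the labelled
#' graph: permuting the input atoms yields the identical serialisation.
#' The step is optional in the generation pipeline and off by default.
#'
#' @param mol a `mol_graph`.
#' @return The reordered graph.
#' @export
canonicalize <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(mol)
  adj <- adjacency(mol)
  heavy <- !is_hydrogen(mol)
  heavy_idx <- which(heavy)
  nh <- length(heavy_idx)
  if (nh == 0) return(mol)
  hmap <- integer(n); hmap[heavy_idx] <- seq_len(nh)
  # heavy-atom adjacency with kekule-independent bond orders
  adjh <- vector("list", nh); ordh <- vector("list", nh)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- hmap[mol$bonds$i[r]]; j <- hmap[mol$bonds$j[r]]
    if (i == 0L || j == 0L) next
    o <- if (isTRUE(mol$bonds$aromatic[r])) 9L else mol$bonds$order[r]
    adjh[[i]] <- c(adjh[[i]], j); ordh[[i]] <- c(ordh[[i]], o)
    adjh[[j]] <- c(adjh[[j]], i); ordh[[j]] <- c(ordh[[j]], o)
  }
  nH_tot <- vapply(heavy_idx, function(a) {
    sum(!heavy[adj[[a]]]) + ifelse(is.na(mol$atoms$nH[a]), 0L, mol$atoms$nH[a])
  }, 0)
  has_stereo <- heavy_idx %in% mol$stereo_atoms$center
  inv <- paste(sprintf("%03d", atomic_number(mol$atoms$element[heavy_idx])),
               sprintf("%+d", mol$atoms$charge[heavy_idx]),
               vapply(adjh, length, 0L), nH_tot,
               as.integer(isTRUE_v(mol$atoms$in_ring[heavy_idx])),
               as.integer(mol$atoms$aromatic[heavy_idx]),
               as.integer(has_stereo))
  base_rank <- match(inv, sort(unique(inv)))
  norm_part <- function(x) match(x, unique(x))
  refine <- function(rank) {
    for (it in seq_len(nh + 1L)) {
      sig <- vapply(seq_len(nh), function(a) {
        key <- sort(paste0(sprintf("%06.1f", rank[adjh[[a]]]), ":", ordh[[a]]))
        paste(sprintf("%06.1f", rank[a]), paste(key, collapse = "|"))
      }, "")
      new_rank <- match(sig, sort(unique(sig)))
      stable <- identical(norm_part(new_rank), norm_part(rank))
      rank <- new_rank
      if (stable) break
    }
    rank
  }
  # serialisation of a discrete candidate ordering (ord[new] = heavy pos)
  serialize_candidate <- function(ord) {
    pos <- integer(nh); pos[ord] <- seq_len(nh)
    bnd <- character(0)
    for (a in seq_len(nh)) {
      for (t in seq_along(adjh[[a]])) {
        b <- adjh[[a]][t]
        if (pos[a] < pos[b]) {
          bnd <- c(bnd, sprintf("%03d-%03d-%d", pos[a], pos[b], ordh[[a]][t]))
        }
      }
    }
    paste(paste(inv[ord], collapse = ","), paste(sort(bnd), collapse = ","),
          sep = ";")
  }
  # individualisation-refinement search for the lexicographically smallest
  # serialisation; symmetric molecules branch over tied cells
  best <- NULL
  best_ord <- NULL
  leaves <- 0L
  search <- function(rank) {
    if (leaves >= 20000L) return()
    rank <- refine(rank)
    if (anyDuplicated(rank) == 0L) {
      leaves <<- leaves + 1L
      ord <- order(rank)
      ser <- serialize_candidate(ord)
      if (is.null(best) || ser < best) {
        best <<- ser
        best_ord <<- ord
      }
      return()
    }
    tied_rank <- min(rank[duplicated(rank) | duplicated(rank, fromLast = TRUE)])
    cell <- which(rank == tied_rank)
    for (a in cell) {
      r2 <- rank * 2
      r2[a] <- r2[a] - 1
      search(r2)
    }
  }
  search(base_rank)
  heavy_ord <- heavy_idx[best_ord]
  # hydrogens follow their (re-ordered) parent atoms
  h_ord <- integer(0)
  for (p in heavy_ord) {
    hs <- adj[[p]][!heavy[adj[[p]]]]
    h_ord <- c(h_ord, sort(hs))
  }
  lone_h <- setdiff(which(!heavy), h_ord)  # e.g. hydride components
  perm <- c(heavy_ord, h_ord, lone_h)      # new position -> old index
  canonical_kekulize(permute_mol(mol, perm))
}

# Deterministic kekulization of aromatic systems: the double bonds of the
# input kekule structure depend on the input atom order, so they are
# re-assigned here by a greedy matching (with backtracking) over the
# aromatic bonds in canonical order. Atoms contributing one pi electron
# (aromatic carbons without an exocyclic double bond, pyridine-type
# nitrogens) must receive exactly one in-system double bond.
canonical_kekulize <- function(mol) {
  arom_rows <- which(isTRUE_v(mol$bonds$aromatic))
  if (!length(arom_rows)) return(mol)
  adj <- adjacency(mol)
  n <- n_atoms(mol)
  needs <- rep(FALSE, n)
  for (a in which(mol$atoms$aromatic)) {
    el <- mol$atoms$element[a]
    chg <- mol$atoms$charge[a]
    exo_dbl <- any(vapply(adj[[a]], function(b) {
      r <- find_bond(mol, a, b)
      mol$bonds$order[r] == 2L && !isTRUE(mol$bonds$aromatic[r])
    }, TRUE))
    deg <- length(adj[[a]]) + ifelse(is.na(mol$atoms$nH[a]), 0L,
                                     mol$atoms$nH[a])
    needs[a] <- if (el == "C") chg == 0L && !exo_dbl
                else if (el == "N") (deg == 2L && chg == 0L) ||
                                    (deg == 3L && chg == 1L)
                else FALSE
  }
  m <- length(arom_rows)
  assign_order <- rep(NA, m)   # TRUE = double
  matched <- rep(FALSE, n)
  solve <- function(k) {
    if (k > m) return(all(!needs | matched))
    r <- arom_rows[k]
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    # try double first (keeps canonical preference stable), then single
    if (needs[i] && needs[j] && !matched[i] && !matched[j]) {
      matched[i] <<- TRUE; matched[j] <<- TRUE
      assign_order[k] <<- TRUE
      if (solve(k + 1)) return(TRUE)
      matched[i] <<- FALSE; matched[j] <<- FALSE
    }
    assign_order[k] <<- FALSE
    # pruning: an unmatched needs-atom with no remaining aromatic bond fails
    if (solve(k + 1)) return(TRUE)
    FALSE
  }
  if (solve(1L)) {
    mol$bonds$order[arom_rows] <- ifelse(assign_order, 2L, 1L)
  }
  mol
}

isTRUE_v <- function(x) !is.na(x) & x

#' Apply an atom permutation to a molecule graph
#'
#' @param mol a `mol_graph`.
#' @param perm integer vector: `perm[new_index] = old_index`.
#' @return Permuted graph with all annotations remapped (stereo parities
#'   adjusted for the reordering of neighbour lists).
#' @export
permute_mol <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, !anyDuplicated(perm))
  inv <- integer(n)
  inv[perm] <- seq_len(n)  # old -> new
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$i <- inv[bonds$i]; bonds$j <- inv[bonds$j]
  ii <- pmin(bonds$i, bonds$j); jj <- pmax(bonds$i, bonds$j)
  bonds$i <- ii; bonds$j <- jj
  ord <- order(bonds$i, bonds$j)
  bonds <- bonds[ord, , drop = FALSE]
  rownames(bonds) <- NULL
  sa <- mol$stereo_atoms
  if (nrow(sa)) {
    sa$center <- inv[sa$center]
    for (col in c("n1", "n2", "n3", "n4")) sa[[col]] <- inv[sa[[col]]]
    sa <- resort_stereo_atoms(sa)
    sa <- sa[order(sa$center), , drop = FALSE]
    rownames(sa) <- NULL
  }
  sb <- mol$stereo_bonds
  if (nrow(sb)) {
    for (col in c("a", "b", "ref_a", "ref_b")) sb[[col]] <- inv[sb[[col]]]
    rownames(sb) <- NULL
  }
  out <- mol_graph(atoms, bonds, name = mol$name,
                   coords = if (is.null(mol$coords)) NULL
                            else mol$coords[perm, , drop = FALSE],
                   stereo_atoms = sa, stereo_bonds = sb)
  out$sssr <- if (is.null(mol$sssr)) NULL else lapply(mol$sssr, function(r) inv[r])
  out
}

#' Full preprocessing pipeline for one compound
#'
#' Perception (hybridisation, SSSR, aromaticity), stereo assignment,
#' hydrogen completion and optional canonical reordering, in the order the
#' generator expects.
#'
#' @param mol raw `mol_graph` from a reader.
#' @param canonical reorder atoms canonically (off by default).
#' @return Preprocessed graph.
#' @export
preprocess <- function(mol, canonical = FALSE) {
  mol <- perceive_atom_properties(mol)
  mol <- add_missing_hydrogens(mol)
  mol <- perceive_atom_properties(mol)
  mol <- assign_stereo(mol)
  if (canonical) {
    mol <- canonicalize(mol)
    mol <- perceive_atom_properties(mol)
  }
  mol
}
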