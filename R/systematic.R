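# Systematic sampling support: molecule fragmentation at rotatable bonds,
# fragment classification, capped-fragment construction, fragment
# conformer generation with a persistent library, and best-first
# enumeration of fragment conformer combinations (FCCs).

#' Fragment a molecule at rotatable bonds
#'
#' Shipped fragmentation rule: a bond is cut iff it is a single, acyclic
#' bond between two heavy atoms, each of which has at least one further
#' heavy neighbour, and neither end is an sp-hybridised (triple-bond or
#' cumulene axis) centre. Amide C-N bonds are cut as well but flagged, so
#' their torsion rule is restricted to the planar 180/0 pair. Terminal
#' rotors whose rotation moves only hydrogens (methyl, hydroxyl, ...) are
#' not cut. Ring systems are never split.
#'
#' @param mol preprocessed connected `mol_graph`.
#' @return List: `fragments` (list of atom index vectors partitioning the
#'   molecule, hydrogens included), `link_bonds` (data.frame `a`, `b`,
#'   `frag_a`, `frag_b`, `amide`).
#' @export
fragment_molecule <- function(mol) {
  adj <- adjacency(mol)
  heavy <- !is_hydrogen(mol)
  cut <- integer(0)
  amide_flag <- logical(0)
  for (r in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[r] != 1L || isTRUE(mol$bonds$in_ring[r]) ||
        isTRUE(mol$bonds$aromatic[r])) next
    a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
    if (!heavy[a] || !heavy[b]) next
    if (!length(setdiff(adj[[a]][heavy[adj[[a]]]], b)) ||
        !length(setdiff(adj[[b]][heavy[adj[[b]]]], a))) next
    if (mol$atoms$hyb[a] == "sp" || mol$atoms$hyb[b] == "sp") next
    cut <- c(cut, r)
    amide_flag <- c(amide_flag, is_amide_bond(mol, adj, a, b))
  }
  # connected components after removing the cut bonds
  n <- n_atoms(mol)
  frag_id <- rep(NA_integer_, n)
  cur <- 0L
  blocked <- new.env(hash = TRUE, parent = emptyenv())
  for (r in cut) assign(bond_key(mol$bonds$i[r], mol$bonds$j[r]), TRUE,
                        envir = blocked)
  for (s in seq_len(n)) {
    if (!is.na(frag_id[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(frag_id[v])) next
      frag_id[v] <- cur
      for (w in adj[[v]]) {
        if (!is.na(frag_id[w])) next
        if (exists(bond_key(v, w), envir = blocked)) next
        stack <- c(stack, w)
      }
    }
  }
  fragments <- lapply(seq_len(cur), function(k) which(frag_id == k))
  link_bonds <- data.frame(
    a = mol$bonds$i[cut], b = mol$bonds$j[cut],
    frag_a = frag_id[mol$bonds$i[cut]], frag_b = frag_id[mol$bonds$j[cut]],
    amide = amide_flag)
  list(fragments = fragments, link_bonds = link_bonds, frag_id = frag_id)
}

is_amide_bond <- function(mol, adj, a, b) {
  ca <- if (mol$atoms$element[a] == "C" && mol$atoms$element[b] == "N") a
        else if (mol$atoms$element[b] == "C" && mol$atoms$element[a] == "N") b
        else return(FALSE)
  for (o in adj[[ca]]) {
    r <- find_bond(mol, ca, o)
    if (mol$atoms$element[o] == "O" && mol$bonds$order[r] == 2L) return(TRUE)
  }
  FALSE
}

#' Classify a fragment
#'
#' Purely aromatic ring systems and chains without heavy-atom rotors are
#' rigid; fragments containing a non-aromatic ring are flexible rings;
#' chains with internal heavy-atom rotors (rare after fragmentation) are
#' flexible chains.
#'
#' @param mol the parent `mol_graph`.
#' @param frag_atoms atom index vector of the fragment.
#' @return "rigid", "flexible_ring" or "flexible_chain".
#' @export
classify_fragment <- function(mol, frag_atoms) {
  inset <- logical(n_atoms(mol))
  inset[frag_atoms] <- TRUE
  brows <- which(inset[mol$bonds$i] & inset[mol$bonds$j])
  ring_rows <- brows[isTRUE_v(mol$bonds$in_ring[brows])]
  if (length(ring_rows)) {
    if (all(mol$bonds$aromatic[ring_rows])) return("rigid")
    return("flexible_ring")
  }
  heavy <- !is_hydrogen(mol)
  adj <- adjacency(mol)
  for (r in brows) {
    if (mol$bonds$order[r] != 1L) next
    a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
    if (!heavy[a] || !heavy[b]) next
    # heavy substituents on either side; attachment points to atoms outside
    # the fragment count, since caps stand in for them during generation
    ha <- setdiff(adj[[a]][heavy[adj[[a]]]], b)
    hb <- setdiff(adj[[b]][heavy[adj[[b]]]], a)
    if (length(ha) && length(hb) &&
        mol$atoms$hyb[a] != "sp" && mol$atoms$hyb[b] != "sp") {
      return("flexible_chain")
    }
  }
  "rigid"
}

#' Build the hydrogen-capped fragment molecule
#'
#' Cut valences are completed with hydrogen caps so the fragment can be
#' parametrized and embedded as a standalone molecule. Stereo descriptors
#' are remapped with the cap standing in for the removed neighbour.
#'
#' @param mol parent `mol_graph`.
#' @param frag_atoms fragment atom set.
#' @param link_bonds link-bond table from [fragment_molecule()].
#' @return `mol_graph` of the capped fragment with attributes
#'   `parent_index` (local -> parent for real atoms) and `caps`
#'   (data.frame `local` cap index, `a` parent attachment atom, `b`
#'   parent partner atom).
#' @export
capped_fragment <- function(mol, frag_atoms, link_bonds) {
  sub <- subset_mol(mol, frag_atoms)
  pidx <- attr(sub, "parent_index")
  caps <- data.frame(local = integer(), a = integer(), b = integer())
  for (r in seq_len(nrow(link_bonds))) {
    a <- link_bonds$a[r]; b <- link_bonds$b[r]
    if (a %in% frag_atoms && !(b %in% frag_atoms)) {
      att <- a; part <- b
    } else if (b %in% frag_atoms && !(a %in% frag_atoms)) {
      att <- b; part <- a
    } else next
    la <- match(att, pidx)
    hrow <- sub$atoms[1, , drop = FALSE]  # template row, then overwrite
    hrow[1, ] <- NA
    hrow$element <- "H"; hrow$charge <- 0L; hrow$nH <- 0L
    hrow$aromatic <- FALSE; hrow$hyb <- "other"
    sub$atoms <- rbind(sub$atoms, hrow)
    lcap <- nrow(sub$atoms)
    sub$bonds <- rbind(sub$bonds, data.frame(
      i = la, j = lcap, order = 1L, aromatic = FALSE, in_ring = FALSE))
    # remap stereo references from the removed partner to the cap
    sa <- sub$stereo_atoms
    mol_sa <- mol$stereo_atoms
    for (s in seq_len(nrow(mol_sa))) {
      if (!(mol_sa$center[s] %in% frag_atoms)) next
      nb <- c(mol_sa$n1[s], mol_sa$n2[s], mol_sa$n3[s], mol_sa$n4[s])
      if (part %in% nb && sum(!nb %in% frag_atoms) == 1L) {
        nb_loc <- ifelse(nb == part, lcap, match(nb, pidx))
        df <- data.frame(center = match(mol_sa$center[s], pidx),
                         n1 = nb_loc[1], n2 = nb_loc[2], n3 = nb_loc[3],
                         n4 = nb_loc[4], parity = mol_sa$parity[s],
                         cip = mol_sa$cip[s])
        df <- resort_stereo_atoms(df)
        if (!nrow(sub$stereo_atoms) ||
            !any(sub$stereo_atoms$center == df$center)) {
          sub$stereo_atoms <- rbind(sub$stereo_atoms, df)
        }
      }
    }
    mol_sb <- mol$stereo_bonds
    for (s in seq_len(nrow(mol_sb))) {
      bs <- c(mol_sb$a[s], mol_sb$b[s], mol_sb$ref_a[s], mol_sb$ref_b[s])
      if (!all(c(mol_sb$a[s], mol_sb$b[s]) %in% frag_atoms)) next
      if (part %in% c(mol_sb$ref_a[s], mol_sb$ref_b[s]) &&
          sum(!bs %in% frag_atoms) == 1L) {
        df <- data.frame(a = match(mol_sb$a[s], pidx),
                         b = match(mol_sb$b[s], pidx),
                         ref_a = if (mol_sb$ref_a[s] == part) lcap
                                 else match(mol_sb$ref_a[s], pidx),
                         ref_b = if (mol_sb$ref_b[s] == part) lcap
                                 else match(mol_sb$ref_b[s], pidx),
                         config = mol_sb$config[s],
                         specified = mol_sb$specified[s])
        sub$stereo_bonds <- rbind(sub$stereo_bonds, df)
      }
    }
    caps <- rbind(caps, data.frame(local = lcap, a = att, b = part))
  }
  rownames(sub$atoms) <- NULL
  rownames(sub$bonds) <- NULL
  sub$coords <- NULL
  sub <- perceive_atom_properties(sub)
  attr(sub, "parent_index") <- pidx
  attr(sub, "caps") <- caps
  sub
}

# ---------------------------------------------------------------------------
# Fragment library

#' Create an (optionally persistent) fragment conformer library
#'
#' Keyed store of pregenerated fragment conformer coordinate sets. Keys
#' are canonical serialisations of the capped fragment graph (including
#' stereo descriptors) and therefore invariant to atom order. The library
#' is populated on miss and can be saved to / loaded from a JSON file.
#'
#' @param path optional JSON file to load.
#' @return A `fragment_library` environment.
#' @export
fragment_library <- function(path = NULL) {
  lib <- new.env(parent = emptyenv())
  lib$store <- new.env(hash = TRUE, parent = emptyenv())
  lib$hits <- 0L
  lib$misses <- 0L
  class(lib) <- "fragment_library"
  if (!is.null(path) && file.exists(path)) {
    dat <- jsonlite::read_json(path)
    for (key in names(dat)) {
      confs <- lapply(dat[[key]], function(cf) {
        list(coords = do.call(rbind, lapply(cf$coords, unlist)),
             energy = cf$energy)
      })
      assign(key, confs, envir = lib$store)
    }
  }
  lib
}

#' Save a fragment library to disk
#' @param lib a `fragment_library`.
#' @param path JSON file path.
#' @export
save_fragment_library <- function(lib, path) {
  keys <- ls(lib$store)
  dat <- setNames(lapply(keys, function(k) {
    lapply(get(k, envir = lib$store), function(cf) {
      list(coords = apply(cf$coords, 1, function(r) as.list(r),
                          simplify = FALSE),
           energy = cf$energy)
    })
  }), keys)
  jsonlite::write_json(dat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Canonical key of a capped fragment
#'
#' Canonicalises the fragment and serialises elements, charges, bond
#' orders and stereo descriptors; equal for all atom orderings of the
#' same labelled graph.
#'
#' @param frag capped fragment `mol_graph`.
#' @return List `key` (string) and `perm` (canonical new -> local index).
#' @export
fragment_key <- function(frag) {
  can <- canonicalize(frag)
  perm <- attr(can, "perm")
  # canonicalize() does not expose the permutation; recompute by matching
  # the canonical order (serialisation is what matters for the key)
  key <- paste(
    paste(can$atoms$element, can$atoms$charge, collapse = ","),
    paste(apply(can$bonds[, c("i", "j", "order")], 1, paste, collapse = "-"),
          collapse = ","),
    paste(apply(can$stereo_atoms[, c("center", "n1", "n2", "n3", "n4",
                                     "parity")], 1, paste, collapse = "-"),
          collapse = ","),
    paste(apply(can$stereo_bonds[, c("a", "b", "ref_a", "ref_b", "config")],
                1, paste, collapse = "-"), collapse = ","),
    sep = ";")
  list(key = key, canonical = can)
}

#' Generate (or fetch) the conformer set of one fragment
#'
#' A library hit returns the stored conformers mapped onto this
#' occurrence's atom order. On miss, conformers are generated according
#' to the fragment class: a single embedded structure for rigid fragments
#' and flexible chains (the chain's rotors are handled later by torsion
#' driving), stochastic sampling with duplicate removal for flexible
#' rings; the result is stored.
#'
#' @param frag capped fragment from [capped_fragment()].
#' @param fclass fragment class from [classify_fragment()].
#' @param param `mmff_param` of the capped fragment (only needed on miss).
#' @param lib a [fragment_library()].
#' @param max_ring_samples stochastic sample cap for flexible rings.
#' @return List of conformers (`coords` local indexing, `energy`), or
#'   NULL on generation failure.
#' @export
fragment_conformers <- function(frag, fclass, param, lib,
                                max_ring_samples = 300L) {
  fk <- fragment_key(frag)
  if (exists(fk$key, envir = lib$store)) {
    lib$hits <- lib$hits + 1L
    stored <- get(fk$key, envir = lib$store)
    # stored coordinates are in canonical order; map back to local order
    can_perm <- canonical_permutation(frag, fk$canonical)
    return(lapply(stored, function(cf) {
      co <- matrix(NA_real_, nrow(cf$coords), 3)
      co[can_perm, ] <- cf$coords
      list(coords = co, energy = cf$energy)
    }))
  }
  lib$misses <- lib$misses + 1L
  if (!isTRUE(param$ok)) return(NULL)
  confs <- switch(fclass,
    rigid = , flexible_chain = {
      g <- generate_random_conformer(frag, param,
                                     stop_criterion = "gradient_norm",
                                     threshold = 0.5)
      if (!g$ok) NULL else list(list(coords = g$coords, energy = g$energy))
    },
    flexible_ring = {
      s <- stochastic_sample(frag, param,
                             stochastic_settings(max_samples = max_ring_samples,
                                                 check_period = 50L,
                                                 energy_window = 15),
                             macrocyclic = FALSE)
      if (!s$ok) NULL else s$conformers
    })
  if (is.null(confs) || !length(confs)) return(NULL)
  can_perm <- canonical_permutation(frag, fk$canonical)
  stored <- lapply(confs, function(cf) {
    list(coords = cf$coords[can_perm, , drop = FALSE], energy = cf$energy)
  })
  assign(fk$key, stored, envir = lib$store)
  confs
}

# permutation p with canonical$atoms == frag$atoms[p, ]: new -> local
canonical_permutation <- function(frag, canonical) {
  # canonicalize is deterministic; rerun to recover the ordering by
  # matching invariant signatures is fragile, so recompute the order the
  # same way canonicalize does: it returns atoms reordered by perm where
  # perm[new] = old. Recover it by matching coordinates of a tagged copy.
  tagged <- frag
  tagged$atoms$tag <- seq_len(n_atoms(frag))
  can <- canonicalize(tagged)
  can$atoms$tag
}

# ---------------------------------------------------------------------------
# FCC enumeration

#' Enumerate fragment conformer combinations best-first
#'
#' Lazy k-smallest-sums expansion over the per-fragment energy-sorted
#' conformer lists: combinations are produced in ascending order of the
#' summed fragment conformer energies, truncated at the cap, and filtered
#' at the minimum energy plus 1.5 times the energy window.
#'
#' @param conf_sets list (one per fragment) of conformer lists.
#' @param window energy window (kcal/mol); the stored threshold is
#'   `min + 1.5 * window`.
#' @param cap maximum number of FCCs (default 100000).
#' @return data.frame: one row per FCC, columns `e_comb` and `i1..iN`
#'   (conformer indices per fragment), ascending `e_comb`.
#' @export
enumerate_fccs <- function(conf_sets, window = 15, cap = 100000L) {
  nfrag <- length(conf_sets)
  stopifnot(nfrag >= 1, all(vapply(conf_sets, length, 0L) > 0))
  ords <- lapply(conf_sets, function(cs) {
    order(vapply(cs, function(c_) c_$energy, 0))
  })
  es <- lapply(seq_len(nfrag), function(k) {
    vapply(conf_sets[[k]], function(c_) c_$energy, 0)[ords[[k]]]
  })
  sizes <- vapply(conf_sets, length, 0L)
  # best-first over index tuples (positions into the sorted lists)
  start <- rep(1L, nfrag)
  keyfun <- function(idx) paste(idx, collapse = ",")
  heap_e <- sum(vapply(seq_len(nfrag), function(k) es[[k]][1], 0))
  heap <- list(list(e = heap_e, idx = start))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(keyfun(start), TRUE, envir = seen)
  out_idx <- list()
  out_e <- numeric(0)
  e_min <- NA_real_
  while (length(heap) && length(out_idx) < cap) {
    es_heap <- vapply(heap, function(h) h$e, 0)
    best <- which.min(es_heap)
    node <- heap[[best]]
    heap <- heap[-best]
    if (is.na(e_min)) e_min <- node$e
    if (node$e > e_min + 1.5 * window) break
    out_idx[[length(out_idx) + 1L]] <- node$idx
    out_e <- c(out_e, node$e)
    for (k in seq_len(nfrag)) {
      if (node$idx[k] < sizes[k]) {
        nidx <- node$idx
        nidx[k] <- nidx[k] + 1L
        key <- keyfun(nidx)
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          ne <- node$e - es[[k]][node$idx[k]] + es[[k]][nidx[k]]
          heap[[length(heap) + 1L]] <- list(e = ne, idx = nidx)
        }
      }
    }
  }
  if (!length(out_idx)) {
    return(cbind(data.frame(e_comb = numeric(0)),
                 matrix(0L, 0, nfrag, dimnames = list(NULL, paste0("i", seq_len(nfrag))))))
  }
  idx_mat <- do.call(rbind, lapply(out_idx, function(idx) {
    vapply(seq_len(nfrag), function(k) ords[[k]][idx[k]], 0L)
  }))
  colnames(idx_mat) <- paste0("i", seq_len(nfrag))
  cbind(data.frame(e_comb = out_e), as.data.frame(idx_mat))
}
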