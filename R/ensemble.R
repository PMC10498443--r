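# Output ensemble compilation: graph automorphism enumeration, Kabsch
# superposition, symmetry-aware minimum RMSD and greedy energy-ordered
# diversity selection.

#' Enumerate topological symmetry mappings
#'
#' All automorphisms of the heavy-atom graph that preserve element,
#' formal charge, total hydrogen count and bond orders, enumerated by
#' colour-refinement-guided backtracking up to a hard cap. The identity
#' mapping is always first; if the cap is hit the (rarely needed) full
#' diversity guarantee of the output selection is relaxed, which is
#' reported through the `capped` attribute.
#'
#' @param mol `mol_graph`.
#' @param cap maximum number of mappings (default 131072).
#' @return List of integer permutation vectors over the heavy-atom
#'   indices (mapping position = source heavy atom, value = image);
#'   attribute `capped` says whether the cap was reached.
#' @export
enumerate_symmetry_mappings <- function(mol, cap = 131072L) {
  heavy <- which(!is_hydrogen(mol))
  nh <- length(heavy)
  hmap <- integer(n_atoms(mol))
  hmap[heavy] <- seq_len(nh)
  adj_full <- adjacency(mol)
  # heavy-atom adjacency with bond orders
  adjh <- vector("list", nh)
  ordh <- vector("list", nh)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[r]; j <- mol$bonds$j[r]
    if (hmap[i] == 0L || hmap[j] == 0L) next
    o <- if (isTRUE(mol$bonds$aromatic[r])) 9L else mol$bonds$order[r]
    adjh[[hmap[i]]] <- c(adjh[[hmap[i]]], hmap[j])
    ordh[[hmap[i]]] <- c(ordh[[hmap[i]]], o)
    adjh[[hmap[j]]] <- c(adjh[[hmap[j]]], hmap[i])
    ordh[[hmap[j]]] <- c(ordh[[hmap[j]]], i = o)
  }
  nH_count <- vapply(heavy, function(a) {
    sum(is_hydrogen(mol)[adj_full[[a]]])
  }, 0L)
  colour <- paste(mol$atoms$element[heavy], mol$atoms$charge[heavy], nH_count,
                  vapply(adjh, length, 0L))
  colour <- match(colour, sort(unique(colour)))
  # refine colours on sorted neighbour (colour:order) multisets; stop on a
  # stable partition (label values may legitimately keep permuting)
  norm_part <- function(x) match(x, unique(x))
  for (it in seq_len(nh + 1L)) {
    sig <- vapply(seq_len(nh), function(a) {
      key <- sort(paste0(colour[adjh[[a]]], ":", ordh[[a]]))
      paste(colour[a], paste(key, collapse = "|"))
    }, "")
    newc <- match(sig, sort(unique(sig)))
    if (identical(norm_part(newc), norm_part(colour))) { colour <- newc; break }
    colour <- newc
  }
  # order atoms for assignment: most-constrained (rarest colour) first
  tab <- table(colour)
  order_by <- order(as.integer(tab[as.character(colour)]), seq_len(nh))
  maps <- list()
  capped <- FALSE
  perm <- integer(nh)
  used <- logical(nh)
  bond_order_h <- function(a, b) {
    idx <- match(b, adjh[[a]])
    if (is.na(idx)) NA_integer_ else ordh[[a]][idx]
  }
  recurse <- function(pos) {
    if (length(maps) >= cap) { capped <<- TRUE; return() }
    if (pos > nh) {
      maps[[length(maps) + 1L]] <<- perm
      return()
    }
    a <- order_by[pos]
    # candidates: same colour, consistent with already-mapped neighbours
    cands <- which(colour == colour[a] & !used)
    # identity-preferred ordering so the identity mapping comes first
    cands <- cands[order(cands != a, cands)]
    for (b in cands) {
      okc <- TRUE
      for (t in seq_along(adjh[[a]])) {
        na <- adjh[[a]][t]
        if (perm[na] != 0L) {
          bo <- bond_order_h(b, perm[na])
          if (is.na(bo) || bo != ordh[[a]][t]) { okc <- FALSE; break }
        }
      }
      if (!okc) next
      perm[a] <<- b
      used[b] <<- TRUE
      recurse(pos + 1L)
      perm[a] <<- 0L
      used[b] <<- FALSE
      if (length(maps) >= cap) { capped <<- TRUE; return() }
    }
  }
  recurse(1L)
  structure(maps, capped = capped, heavy = heavy)
}

#' Kabsch minimum-RMSD superposition
#'
#' Minimal least-squares RMSD between two coordinate sets over proper
#' rotations and translations (closed-form SVD solution; reflections are
#' excluded).
#'
#' @param a,b M x 3 coordinate matrices (equal row counts, M >= 1).
#' @param mapping optional permutation applied to the rows of `b`.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, mapping = NULL) {
  if (!is.null(mapping)) b <- b[mapping, , drop = FALSE]
  stopifnot(nrow(a) == nrow(b), nrow(a) >= 1)
  if (nrow(a) == 1) return(0)
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  h <- crossprod(cb, ca)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- c(1, 1, d)
  rot <- sv$v %*% diag(s) %*% t(sv$u)
  diff <- ca - cb %*% t(rot)
  sqrt(sum(diff^2) / nrow(a))
}

#' Symmetry-aware minimum RMSD between two conformers
#'
#' Minimum heavy-atom Kabsch RMSD over all topological symmetry mappings
#' (up to the cap). Hydrogens are excluded. The result under different
#' optimal mappings is not a metric (no triangle inequality is implied).
#'
#' @param mol `mol_graph` the conformers belong to.
#' @param coords_a,coords_b full N x 3 coordinate matrices.
#' @param mappings precomputed result of [enumerate_symmetry_mappings()]
#'   (computed on the fly if NULL).
#' @return Minimum RMSD (Angstrom).
#' @export
min_symmetry_rmsd <- function(mol, coords_a, coords_b, mappings = NULL) {
  if (is.null(mappings)) mappings <- enumerate_symmetry_mappings(mol)
  heavy <- attr(mappings, "heavy")
  a <- coords_a[heavy, , drop = FALSE]
  b <- coords_b[heavy, , drop = FALSE]
  best <- Inf
  for (p in mappings) {
    r <- kabsch_rmsd(a[p, , drop = FALSE], b)
    if (r < best) best <- r
  }
  best
}

#' Output-ensemble selection settings
#'
#' @param rmsd_threshold minimum pairwise symmetry-aware heavy-atom RMSD
#'   between output conformers (Angstrom, default 0.5).
#' @param n_max maximum output ensemble size.
#' @param energy_window maximum energy above the ensemble minimum
#'   (kcal/mol; 15 is the systematic-sampling default).
#' @param include_input include the input 3D structure as a candidate.
#' @param mapping_cap symmetry-mapping cap (default 131072).
#' @return A `selection_settings` list.
#' @export
selection_settings <- function(rmsd_threshold = 0.5, n_max = 100L,
                               energy_window = 15, include_input = FALSE,
                               mapping_cap = 131072L) {
  stopifnot(rmsd_threshold > 0, n_max >= 1)
  structure(list(rmsd_threshold = rmsd_threshold, n_max = as.integer(n_max),
                 energy_window = energy_window,
                 include_input = include_input,
                 mapping_cap = as.integer(mapping_cap)),
            class = "selection_settings")
}

#' Compile the final output conformer ensemble
#'
#' Candidates are ranked by increasing energy and picked greedily: a
#' conformer is accepted when its symmetry-aware heavy-atom RMSD to every
#' previously selected conformer reaches the threshold. Selection stops
#' at the ensemble size cap or when the energy window above the minimum is
#' exceeded. An optional input structure is inserted as the first
#' candidate before ranking-based picking (window and diversity rules then
#' apply to it as to any candidate).
#'
#' @param mol `mol_graph`.
#' @param candidates list of conformers (`$coords`, `$energy`).
#' @param settings a [selection_settings()] object.
#' @param input_structure optional list(`coords`, `energy`).
#' @return A `conformer_ensemble`: `mol`, energy-ordered `conformers`,
#'   `mapping_capped` flag.
#' @export
compile_output_ensemble <- function(mol, candidates,
                                    settings = selection_settings(),
                                    input_structure = NULL) {
  if (!length(candidates) && is.null(input_structure)) {
    stop("no candidate conformers to compile", call. = FALSE)
  }
  e <- vapply(candidates, function(c_) c_$energy, 0)
  ord <- order(e)
  candidates <- candidates[ord]
  if (!is.null(input_structure)) {
    candidates <- c(list(input_structure), candidates)
  }
  mappings <- enumerate_symmetry_mappings(mol, settings$mapping_cap)
  e_min <- min(vapply(candidates, function(c_) c_$energy, 0))
  selected <- list()
  for (cand in candidates) {
    if (length(selected) >= settings$n_max) break
    if (cand$energy > e_min + settings$energy_window) {
      if (length(selected)) break else next
    }
    ok <- TRUE
    for (s in selected) {
      if (min_symmetry_rmsd(mol, cand$coords, s$coords, mappings) <
          settings$rmsd_threshold) { ok <- FALSE; break }
    }
    if (ok) selected[[length(selected) + 1L]] <- cand
  }
  sel_e <- vapply(selected, function(c_) c_$energy, 0)
  selected <- selected[order(sel_e)]
  structure(list(mol = mol, conformers = selected,
                 mapping_capped = attr(mappings, "capped")),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  e <- vapply(x$conformers, function(c_) c_$energy, 0)
  cat(sprintf("<conformer_ensemble> %s: %d conformer(s), E %.3f .. %.3f kcal/mol\n",
              if (nzchar(x$mol$name)) x$mol$name else "(unnamed)",
              length(e), if (length(e)) min(e) else NA,
              if (length(e)) max(e) else NA))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$conformers)
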