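# Torsion-rule libraries: SMARTS-keyed lists of preferred dihedral angles
# with tolerance intervals, first-match semantics, user libraries searched
# before the built-in one, and a hybridisation-based terminal fallback.

#' Load a torsion-rule library
#'
#' Plain-text format, one rule per line: `SMARTS<TAB>angle:tol[,angle:tol...]`
#' (`#` comments allowed). Patterns describe a linear path of three or four
#' atoms; the rotor is the bond between atoms 2 and 3 of a four-atom path
#' and between atoms 1 and 2 of a three-atom path. Angles are normalised
#' to [0, 360).
#'
#' @param path file path; the shipped built-in library by default.
#' @return A `torsion_library`: list of rules (`smarts`, `angles`,
#'   `tolerances`).
#' @export
load_torsion_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "torsion-lib.tsv", package = "confsmith")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  rules <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 2) stop("bad torsion library line: ", ln)
    ent <- strsplit(strsplit(parts[2], ",")[[1]], ":")
    ang <- vapply(ent, function(e) as.numeric(e[1]), 0) %% 360
    tol <- vapply(ent, function(e) if (length(e) > 1) as.numeric(e[2]) else 20, 0)
    list(smarts = parts[1], angles = ang, tolerances = tol)
  })
  structure(list(rules = rules, path = path), class = "torsion_library")
}

torsion_library_smarts <- function(libs) {
  unlist(lapply(libs, function(l) {
    vapply(l$rules, function(r) r$smarts, "")
  }), use.names = FALSE)
}

#' Match torsion rules against a rotor bond
#'
#' Libraries are consulted in order (user libraries before the built-in
#' one), rules within each in file order; the first rule with a
#' substructure match whose rotor bond equals the query bond wins. The
#' hybridisation-based fallback guarantees a nonempty result: staggered
#' angles (60, 180, 300) for sp3-sp3 bonds, (0, 180) for sp2-sp2 and a
#' 60-degree grid otherwise.
#'
#' @param mol `mol_graph`.
#' @param bond length-2 integer vector (rotor bond atoms).
#' @param libs list of `torsion_library` objects, highest precedence first.
#' @param matches precomputed SMARTS matches for the concatenated rules of
#'   `libs` (from [parametrize()]'s `smarts_matches`); list parallel to
#'   the concatenated rule sequence, each a list of matched atom tuples.
#' @return List `angles`, `tolerances`, `rule` (index into the
#'   concatenated rule list; NA for the fallback).
#' @export
match_torsion_rules <- function(mol, bond, libs, matches) {
  rules <- unlist(lapply(libs, function(l) l$rules), recursive = FALSE)
  for (k in seq_along(rules)) {
    ms <- if (k <= length(matches)) matches[[k]] else list()
    for (tup in ms) {
      rb <- if (length(tup) >= 4) tup[2:3] else tup[1:2]
      if (all(sort(rb) == sort(bond))) {
        return(list(angles = rules[[k]]$angles,
                    tolerances = rules[[k]]$tolerances, rule = k))
      }
    }
  }
  hyb <- mol$atoms$hyb[bond]
  if (all(hyb == "sp3")) {
    list(angles = c(60, 180, 300), tolerances = c(20, 20, 20), rule = NA)
  } else if (all(hyb == "sp2")) {
    list(angles = c(0, 180), tolerances = c(20, 20), rule = NA)
  } else {
    list(angles = seq(0, 300, by = 60), tolerances = rep(20, 6), rule = NA)
  }
}

#' Expand angles by their first tolerance interval
#'
#' When tolerance-range sampling is enabled, every listed angle `a` with
#' first tolerance `t` contributes the triple `a - t`, `a`, `a + t`
#' (normalised, de-duplicated). Disabled by default.
#'
#' @param rule list with `angles` and `tolerances`.
#' @param enabled tolerance-range sampling flag.
#' @return Numeric vector of angles in [0, 360).
#' @export
expand_tolerance_angles <- function(rule, enabled = FALSE) {
  if (!enabled) return(rule$angles)
  ang <- as.vector(rbind(rule$angles - rule$tolerances, rule$angles,
                         rule$angles + rule$tolerances)) %% 360
  ang[!duplicated(round(ang, 6))]
}

#' Reduce angles equivalent under local rotational symmetry
#'
#' When the rotating side of a bond has k-fold rotational symmetry about
#' the bond axis (k = 2 or 3; e.g. phenyl, nitro, trifluoromethyl,
#' tert-butyl), angles equal modulo 360/k generate duplicate conformers
#' and are collapsed to one representative. Symmetry is detected from the
#' graph: the attachment atom must carry exactly k off-axis substituents
#' lying in one automorphism orbit of the side subgraph, with the
#' geometric compatibility conditions (sp3 centre for k = 3; sp2/aromatic
#' centre with an aromatic or single-atom-pair side for k = 2).
#'
#' @param mol `mol_graph`.
#' @param bond rotor bond (a, b): the side of `b` is the rotating side by
#'   convention, but both sides are checked.
#' @param side_atoms_a,side_atoms_b atom sets on each side of the bond.
#' @param angles angle vector to reduce.
#' @return Reduced angle vector.
#' @export
reduce_symmetric_angles <- function(mol, bond, side_atoms_a, side_atoms_b,
                                    angles) {
  k <- max(axis_symmetry_order(mol, bond[1], bond[2], side_atoms_a),
           axis_symmetry_order(mol, bond[2], bond[1], side_atoms_b))
  if (k <= 1) return(angles)
  period <- 360 / k
  red <- angles %% period
  angles[!duplicated(round(red, 6))]
}

# k-fold rotational symmetry of the side rooted at attachment atom `a`
# (bonded to `b` across the rotor bond)
axis_symmetry_order <- function(mol, a, b, side_atoms) {
  adj <- adjacency(mol)
  subs <- setdiff(adj[[a]], b)
  t <- length(subs)
  if (!(t %in% c(2L, 3L))) return(1L)
  heavy_subs <- subs[!is_hydrogen(mol)[subs]]
  if (t == 3L) {
    if (mol$atoms$hyb[a] != "sp3") return(1L)
    if (length(heavy_subs) == 0L) return(3L)             # methyl-like
    if (length(heavy_subs) != 3L) return(1L)
  } else {
    if (!(mol$atoms$hyb[a] == "sp2" || mol$atoms$aromatic[a])) return(1L)
    if (length(heavy_subs) == 0L) return(2L)
    if (length(heavy_subs) != 2L) return(1L)
    aromatic_side <- all(mol$atoms$aromatic[setdiff(
      side_atoms[!is_hydrogen(mol)[side_atoms]], a)])
    single_pair <- all(vapply(heavy_subs, function(s)
      length(adj[[s]]) == 1L, TRUE))
    if (!aromatic_side && !single_pair) return(1L)
  }
  # all heavy substituents must lie in one orbit of the side subgraph
  side <- sort(unique(c(a, side_atoms)))
  sub <- subset_mol(mol, side)
  pidx <- attr(sub, "parent_index")
  loc <- match(heavy_subs, pidx)
  loc_a <- match(a, pidx)
  maps <- enumerate_symmetry_mappings(sub, cap = 2000L)
  heavy_loc <- attr(maps, "heavy")
  pos <- match(loc, heavy_loc)
  pos_a <- match(loc_a, heavy_loc)
  target <- if (t == 3L) 3L else 2L
  for (p in maps) {
    if (!is.na(pos_a) && p[pos_a] != pos_a) next
    img <- p[pos]
    if (any(img != pos) && setequal(img, pos)) {
      # nontrivial permutation of the substituents about the axis
      if (target == 2L) return(2L)
      # for threefold require a 3-cycle
      if (all(img != pos)) return(3L)
    }
  }
  1L
}
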