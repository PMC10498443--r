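# MMFF94 parametrisation and decomposed energy evaluation.
#
# Interaction perception and parameter assignment are delegated to the
# validated RDKit MMFF94/MMFF94s implementation (via the bundled helper);
# this module owns the decomposed-term representation, the variant flags,
# the energy/gradient evaluation (compiled, see src/energy.cpp) and the
# optional refined-torsion override mechanism.

#' Parametrize molecules with MMFF94
#'
#' Assigns MMFF94 (or MMFF94s) atom types, partial charges and all
#' interaction parameters to hydrogen-complete molecules, returning the
#' decomposed interaction lists used throughout the generator: bond
#' stretching, angle bending, stretch-bend, out-of-plane bending, torsion,
#' and topological-distance-gated nonbonded pairs (van der Waals +
#' electrostatics; pairs closer than three bonds excluded, 1-4
#' electrostatics scaled by 0.75). With `no_estat = TRUE` the
#' electrostatic contribution is dropped (charge products zeroed), the
#' variant used for systematic sampling of drug-like molecules.
#'
#' @param mols list of preprocessed `mol_graph` objects (or a single one).
#' @param variant "MMFF94s" (static: planar delocalised nitrogens) or
#'   "MMFF94".
#' @param no_estat drop electrostatic interactions.
#' @param torsion_smarts character vector of SMARTS patterns to match
#'   (torsion-rule assignment); matches are stored on each result.
#' @return List of `mmff_param` objects (or a single one if `mols` was
#'   a single molecule). Failed molecules yield an object with
#'   `$ok = FALSE` and `$error` naming the problem.
#' @export
parametrize <- function(mols, variant = c("MMFF94s", "MMFF94"),
                        no_estat = FALSE, torsion_smarts = character()) {
  variant <- match.arg(variant)
  single <- inherits(mols, "mol_graph")
  if (single) mols <- list(mols)
  blocks <- vapply(mols, function(m) write_molblock(m), "")
  res <- bridge_call(list(cmd = "params", molblocks = as.list(blocks),
                          variant = variant,
                          smarts = as.list(torsion_smarts)))
  out <- lapply(seq_along(res), function(k) {
    x <- res[[k]]
    if (!isTRUE(x$ok)) {
      return(structure(list(ok = FALSE, error = x$error %||% "parametrization failed",
                            natoms = n_atoms(mols[[k]])),
                       class = "mmff_param"))
    }
    tomat <- function(lst, ncol) {
      if (!length(lst)) return(matrix(0, 0, ncol))
      m <- do.call(rbind, lapply(lst, function(row) as.numeric(unlist(row))))
      m
    }
    bonds <- tomat(x$bonds, 4);  if (nrow(bonds))  bonds[, 1:2] <- bonds[, 1:2] + 1
    angles <- tomat(x$angles, 6); if (nrow(angles)) angles[, 1:3] <- angles[, 1:3] + 1
    sb <- tomat(x$sb, 8);        if (nrow(sb))     sb[, 1:3] <- sb[, 1:3] + 1
    oop <- tomat(x$oop, 5);      if (nrow(oop))    oop[, 1:4] <- oop[, 1:4] + 1
    tors <- tomat(x$tors, 7);    if (nrow(tors))   tors[, 1:4] <- tors[, 1:4] + 1
    nb <- tomat(x$nb, 6);        if (nrow(nb))     nb[, 1:2] <- nb[, 1:2] + 1
    if (no_estat && nrow(nb)) nb[, 5] <- 0
    matches <- NULL
    if (length(torsion_smarts)) {
      matches <- lapply(x$matches, function(ms) {
        if (is.null(ms)) return(list())
        lapply(ms, function(m) as.integer(unlist(m)) + 1L)
      })
    }
    structure(list(ok = TRUE, natoms = n_atoms(mols[[k]]), variant = variant,
                   no_estat = no_estat,
                   atom_types = as.integer(unlist(x$atom_types)),
                   charges = as.numeric(unlist(x$charges)),
                   bonds = bonds, angles = angles, sb = sb, oop = oop,
                   tors = tors, nb = nb, smarts_matches = matches),
              class = "mmff_param")
  })
  if (single) out[[1]] else out
}

#' @export
print.mmff_param <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("<mmff_param> FAILED:", x$error, "\n")
  } else {
    cat(sprintf("<mmff_param> %s%s: %d atoms, %d bonds, %d angles, %d torsions, %d nonbonded pairs\n",
                x$variant, if (x$no_estat) " (no electrostatics)" else "",
                x$natoms, nrow(x$bonds), nrow(x$angles), nrow(x$tors),
                nrow(x$nb)))
  }
  invisible(x)
}

#' MMFF94 energy with per-category breakdown
#'
#' @param param an `mmff_param`.
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @return An `energy_breakdown`: per-category sums (kcal/mol) for
#'   stretching, bending, stretch-bend, out-of-plane, torsion, van der
#'   Waals and electrostatic interactions, plus `total` (their exact sum).
#'   Coincident nonbonded pairs give a large finite penalty, never a
#'   non-finite value.
#' @export
mmff_energy <- function(param, coords) {
  stopifnot(isTRUE(param$ok), nrow(coords) == param$natoms)
  res <- cpp_mmff_energy(coords, param$bonds, param$angles, param$sb,
                         param$oop, param$tors, param$nb, FALSE)
  structure(res, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (nm in setdiff(names(x), "gradient")) {
    cat(sprintf("  %-14s %12.4f kcal/mol\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' MMFF94 energy gradient
#'
#' @inheritParams mmff_energy
#' @return N x 3 matrix of dE/dx (kcal/mol/Angstrom).
#' @export
mmff_gradient <- function(param, coords) {
  stopifnot(isTRUE(param$ok), nrow(coords) == param$natoms)
  res <- cpp_mmff_energy(coords, param$bonds, param$angles, param$sb,
                         param$oop, param$tors, param$nb, TRUE)
  res$gradient
}

mmff_energy_grad <- function(param, coords) {
  res <- cpp_mmff_energy(coords, param$bonds, param$angles, param$sb,
                         param$oop, param$tors, param$nb, TRUE)
  res
}

#' Load refined torsion parameter overrides
#'
#' Plain-text file, one override per line: four MMFF94 numeric atom types
#' followed by V1 V2 V3 (whitespace-separated; `#` comments allowed).
#' Applied with [apply_torsion_overrides()]; matching is by the atom-type
#' quadruple in either direction. No override file is shipped: the table
#' is empty by default.
#'
#' @param path file path.
#' @return data.frame with columns t1..t4, V1..V3.
#' @export
load_torsion_overrides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(t1 = integer(), t2 = integer(), t3 = integer(),
                      t4 = integer(), V1 = numeric(), V2 = numeric(),
                      V3 = numeric()))
  }
  vals <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  stopifnot(ncol(vals) == 7)
  data.frame(t1 = as.integer(vals[, 1]), t2 = as.integer(vals[, 2]),
             t3 = as.integer(vals[, 3]), t4 = as.integer(vals[, 4]),
             V1 = vals[, 5], V2 = vals[, 6], V3 = vals[, 7])
}

#' Apply torsion parameter overrides to a parametrisation
#'
#' @param param an `mmff_param`.
#' @param overrides data.frame from [load_torsion_overrides()].
#' @return The modified parametrisation.
#' @export
apply_torsion_overrides <- function(param, overrides) {
  if (!isTRUE(param$ok) || !nrow(overrides) || !nrow(param$tors)) return(param)
  at <- param$atom_types
  for (r in seq_len(nrow(param$tors))) {
    q <- at[param$tors[r, 1:4]]
    hit <- which((overrides$t1 == q[1] & overrides$t2 == q[2] &
                  overrides$t3 == q[3] & overrides$t4 == q[4]) |
                 (overrides$t1 == q[4] & overrides$t2 == q[3] &
                  overrides$t3 == q[2] & overrides$t4 == q[1]))
    if (length(hit)) {
      param$tors[r, 5:7] <- c(overrides$V1[hit[1]], overrides$V2[hit[1]],
                              overrides$V3[hit[1]])
    }
  }
  param
}
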