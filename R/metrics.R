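# Benchmarking protocol: per-molecule best RMSD against a reference
# structure (symmetry-aware, heavy atoms only, optionally restricted to
# the macrocyclic ring) and summary/percentile tables.

#' Best RMSD of an ensemble against a reference structure
#'
#' Minimum heavy-atom RMSD between the reference coordinates and any
#' ensemble conformer, minimised over all topological symmetry mappings.
#' With `ring_only = TRUE` the comparison is restricted to the heavy
#' atoms of macrocyclic rings (rings with more than 10 nonaromatic single
#' bonds).
#'
#' @param ensemble a `conformer_ensemble` (or plain list of conformers
#'   with a `mol` supplied).
#' @param reference_coords N x 3 matrix over the same atom graph.
#' @param mol molecule graph (defaults to `ensemble$mol`).
#' @param ring_only restrict to macrocyclic ring atoms.
#' @param cap symmetry-mapping cap.
#' @return Best RMSD in Angstrom.
#' @export
best_rmsd <- function(ensemble, reference_coords, mol = NULL,
                      ring_only = FALSE, cap = 131072L) {
  if (is.null(mol)) mol <- ensemble$mol
  conformers <- if (inherits(ensemble, "conformer_ensemble"))
    ensemble$conformers else ensemble
  if (!length(conformers)) stop("empty ensemble", call. = FALSE)
  if (nrow(reference_coords) != n_atoms(mol)) {
    stop("reference does not match the molecule's atom graph", call. = FALSE)
  }
  mappings <- enumerate_symmetry_mappings(mol, cap)
  heavy <- attr(mappings, "heavy")
  subset <- seq_along(heavy)
  if (ring_only) {
    if (is.null(mol$sssr)) mol <- perceive_atom_properties(mol)
    ring_atoms <- integer(0)
    for (ring in mol$sssr) {
      nr <- length(ring)
      cnt <- sum(vapply(seq_len(nr), function(t) {
        b <- find_bond(mol, ring[t], ring[if (t == nr) 1L else t + 1L])
        mol$bonds$order[b] == 1L && !isTRUE(mol$bonds$aromatic[b])
      }, TRUE))
      if (cnt > 10L) ring_atoms <- union(ring_atoms, ring)
    }
    if (!length(ring_atoms)) stop("no macrocyclic ring atoms", call. = FALSE)
    subset <- which(heavy %in% ring_atoms)
  }
  ref <- reference_coords[heavy, , drop = FALSE]
  best <- Inf
  for (conf in conformers) {
    co <- conf$coords[heavy, , drop = FALSE]
    for (p in mappings) {
      # the mapping must keep the compared subset within itself
      if (ring_only && !all(p[subset] %in% subset)) next
      r <- kabsch_rmsd(co[p, , drop = FALSE][subset, , drop = FALSE],
                       ref[subset, , drop = FALSE])
      if (r < best) best <- r
    }
  }
  best
}

#' Summarise benchmark records
#'
#' @param records data.frame with columns `name`, `best_rmsd`,
#'   `n_conformers`, `time`, `status` ("ok" records enter the statistics;
#'   failures are counted separately).
#' @param thresholds RMSD thresholds (Angstrom) for the percentile table.
#' @return List `stats` (mean/median/min/max of best RMSD, ensemble size,
#'   time, counts), `percentiles` (data.frame threshold, percent of ok
#'   records at or below), `n_failed`. All-failed input yields
#'   `stats = NULL` with the failure count.
#' @export
summarize_benchmark <- function(records, thresholds = c(0.5, 1.0, 1.5, 2.0)) {
  ok <- records[records$status == "ok", , drop = FALSE]
  n_failed <- sum(records$status != "ok")
  if (!nrow(ok)) {
    return(list(stats = NULL, percentiles = NULL, n_failed = n_failed))
  }
  stats <- list(
    n = nrow(ok),
    mean_rmsd = mean(ok$best_rmsd),
    median_rmsd = median(ok$best_rmsd),
    min_rmsd = min(ok$best_rmsd),
    max_rmsd = max(ok$best_rmsd),
    mean_n_conformers = mean(ok$n_conformers),
    mean_time = mean(ok$time))
  percentiles <- data.frame(
    threshold = thresholds,
    percent = vapply(thresholds, function(t) {
      100 * mean(ok$best_rmsd < t)
    }, 0))
  list(stats = stats, percentiles = percentiles, n_failed = n_failed)
}
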