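# Per-compound orchestration: sampling-mode selection, per-component
# generation, multi-component assembly, timeout and failure accounting.

#' Conformer generation settings
#'
#' @param mode "auto" (stochastic for macrocycles, systematic otherwise),
#'   "systematic" or "stochastic" for all inputs.
#' @param energy_window kcal/mol; `NA` selects the mode default (15 for
#'   systematic, 20 for stochastic runs).
#' @param rmsd_threshold output diversity threshold (Angstrom).
#' @param n_max maximum output ensemble size.
#' @param time_budget per-molecule budget in seconds (0 = disabled).
#' @param seed RNG seed.
#' @param canonical canonicalize connection tables before generation.
#' @param tolerance_sampling torsion tolerance-range sampling.
#' @param include_input include the input 3D structure as a candidate.
#' @param torsion_libs paths of user torsion libraries (searched before
#'   the built-in one, in the given order).
#' @param frag_lib_path optional fragment-library JSON to preload.
#' @param variant MMFF94 variant.
#' @param max_samples,check_period stochastic loop controls.
#' @return A `generation_settings` list.
#' @export
generation_settings <- function(mode = c("auto", "systematic", "stochastic"),
                                energy_window = NA, rmsd_threshold = 0.5,
                                n_max = 100L, time_budget = 0, seed = 1L,
                                canonical = FALSE, tolerance_sampling = FALSE,
                                include_input = FALSE,
                                torsion_libs = character(),
                                frag_lib_path = NULL,
                                variant = "MMFF94s",
                                max_samples = 2000L, check_period = 100L) {
  mode <- match.arg(mode)
  stopifnot(time_budget >= 0, n_max >= 1)
  structure(list(mode = mode, energy_window = energy_window,
                 rmsd_threshold = rmsd_threshold, n_max = as.integer(n_max),
                 time_budget = time_budget, seed = as.integer(seed),
                 canonical = canonical,
                 tolerance_sampling = tolerance_sampling,
                 include_input = include_input, torsion_libs = torsion_libs,
                 frag_lib_path = frag_lib_path, variant = variant,
                 max_samples = as.integer(max_samples),
                 check_period = as.integer(check_period)),
            class = "generation_settings")
}

#' Detect a macrocyclic ring system
#'
#' TRUE iff some SSSR ring contains more than 10 nonaromatic single
#' bonds; such molecules are routed to stochastic sampling in auto mode.
#'
#' @param mol perceived `mol_graph`.
#' @return Logical flag.
#' @export
detect_macrocycle <- function(mol) {
  if (is.null(mol$sssr)) mol <- perceive_atom_properties(mol)
  for (ring in mol$sssr) {
    nr <- length(ring)
    cnt <- 0L
    for (t in seq_len(nr)) {
      b <- find_bond(mol, ring[t], ring[if (t == nr) 1L else t + 1L])
      if (mol$bonds$order[b] == 1L && !isTRUE(mol$bonds$aromatic[b])) {
        cnt <- cnt + 1L
      }
    }
    if (cnt > 10L) return(TRUE)
  }
  FALSE
}

load_user_libraries <- function(settings) {
  libs <- lapply(settings$torsion_libs, load_torsion_library)
  c(libs, list(load_torsion_library()))
}

#' Generate the conformer ensemble of one compound
#'
#' Top-level workflow: preprocessing (optional canonicalization), then a
#' separate conformer ensemble per component with automatic
#' systematic/stochastic selection (overridable), and compilation of the
#' output ensemble. Multi-component compounds are assembled by
#' translating component conformers apart along the x axis with a 5
#' Angstrom bounding-box gap (a documented naive placement) and pairing
#' the i-th conformers up to the shortest component ensemble. Failures at
#' any stage downgrade to a failed report record and never raise.
#'
#' @param compound raw `mol_graph` from a reader.
#' @param settings a [generation_settings()] object.
#' @param lib optional [fragment_library()] shared across calls.
#' @return List `ensemble` (a `conformer_ensemble`, or NULL on failure)
#'   and `report` (status, time, sizes, log).
#' @export
generate_conformers <- function(compound, settings = generation_settings(),
                                lib = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  fail <- function(stage, msg) {
    list(ensemble = NULL,
         report = list(status = paste0("failed:", stage),
                       time = as.numeric(Sys.time() - t0, units = "secs"),
                       n_conformers = 0L,
                       log = c(log, paste0("ERROR [", stage, "] ", msg))))
  }
  elapsed <- function() as.numeric(Sys.time() - t0, units = "secs")
  over_budget <- function() {
    settings$time_budget > 0 && elapsed() > settings$time_budget
  }
  if (is.null(lib)) lib <- fragment_library(settings$frag_lib_path)
  set.seed(settings$seed)
  mol <- try(preprocess(compound, canonical = settings$canonical),
             silent = TRUE)
  if (inherits(mol, "try-error")) {
    return(fail("preprocessing", attr(mol, "condition")$message))
  }
  ncomp <- n_components(mol)
  log <- c(log, sprintf("compound '%s': %d atom(s), %d component(s)",
                        mol$name, n_atoms(mol), ncomp))
  libs <- load_user_libraries(settings)
  comp_ens <- vector("list", ncomp)
  comp_maps <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    if (over_budget()) {
      return(list(ensemble = NULL,
                  report = list(status = "timeout", time = elapsed(),
                                n_conformers = 0L, log = log)))
    }
    cm <- get_component(mol, k)
    comp_maps[[k]] <- attr(cm, "parent_index")
    cm <- perceive_atom_properties(cm)
    if (n_atoms(cm) == 1L) {
      # monoatomic component (counter ion): a single trivial conformer
      comp_ens[[k]] <- list(list(coords = matrix(0, 1, 3), energy = 0))
      log <- c(log, sprintf("component %d: monoatomic", k))
      next
    }
    macro <- detect_macrocycle(cm)
    mode <- if (settings$mode != "auto") settings$mode
            else if (macro) "stochastic" else "systematic"
    log <- c(log, sprintf("component %d: %d atoms, macrocyclic=%s, path=%s",
                          k, n_atoms(cm), macro, mode))
    window <- settings$energy_window
    if (is.na(window)) window <- if (mode == "stochastic") 20 else 15
    no_estat <- mode == "systematic"
    if (mode == "systematic") {
      fr <- fragment_molecule(cm)
      param <- try(parametrize(cm, variant = settings$variant,
                               no_estat = no_estat,
                               torsion_smarts = torsion_library_smarts(libs)),
                   silent = TRUE)
      if (inherits(param, "try-error") || !isTRUE(param$ok)) {
        return(fail("parametrization",
                    if (inherits(param, "try-error")) "helper error"
                    else param$error))
      }
      fp <- try(prepare_systematic(cm, fr, variant = settings$variant,
                                   no_estat = no_estat), silent = TRUE)
      if (inherits(fp, "try-error")) {
        return(fail("parametrization", "fragment parametrization error"))
      }
      res <- systematic_sample(cm, param, fp, fr, libs, lib = lib,
                               window = window,
                               tolerance_sampling = settings$tolerance_sampling)
      log <- c(log, sprintf("component %d: systematic: %s", k, res$detail))
    } else {
      param <- try(parametrize(cm, variant = settings$variant,
                               no_estat = FALSE), silent = TRUE)
      if (inherits(param, "try-error") || !isTRUE(param$ok)) {
        return(fail("parametrization",
                    if (inherits(param, "try-error")) "helper error"
                    else param$error))
      }
      remaining <- if (settings$time_budget > 0)
        max(settings$time_budget - elapsed(), 1) else 0
      ss <- stochastic_settings(max_samples = settings$max_samples,
                                check_period = settings$check_period,
                                energy_window = window,
                                time_budget = remaining)
      res <- stochastic_sample(cm, param, ss, macrocyclic = macro)
      log <- c(log, sprintf("component %d: stochastic: %d cycles, converged=%s",
                            k, res$cycles, res$converged))
    }
    if (!res$ok || !length(res$conformers)) {
      return(fail("sampling", "no conformers generated"))
    }
    input_structure <- NULL
    if (settings$include_input && !is.null(cm$coords) &&
        !anyNA(cm$coords)) {
      input_structure <- list(coords = cm$coords,
                              energy = mmff_energy(param, cm$coords)$total)
    }
    sel <- selection_settings(rmsd_threshold = settings$rmsd_threshold,
                              n_max = settings$n_max,
                              energy_window = window)
    comp_ens[[k]] <- compile_output_ensemble(cm, res$conformers, sel,
                                             input_structure)$conformers
    log <- c(log, sprintf("component %d: %d output conformer(s)",
                          k, length(comp_ens[[k]])))
  }
  # assemble components into compound conformers
  n_out <- min(vapply(comp_ens, length, 0L))
  confs <- vector("list", n_out)
  for (t in seq_len(n_out)) {
    coords <- matrix(NA_real_, n_atoms(mol), 3)
    energy <- 0
    x_off <- 0
    for (k in seq_len(ncomp)) {
      cc <- comp_ens[[k]][[t]]$coords
      cc <- sweep(cc, 2, apply(cc, 2, min))  # bounding box at origin
      cc[, 1] <- cc[, 1] + x_off
      x_off <- max(cc[, 1]) + 5
      coords[comp_maps[[k]], ] <- cc
      energy <- energy + comp_ens[[k]][[t]]$energy
    }
    confs[[t]] <- list(coords = coords, energy = energy)
  }
  if (ncomp == 1L) {
    confs <- comp_ens[[1]]
  }
  ens <- structure(list(mol = mol, conformers = confs,
                        mapping_capped = FALSE),
                   class = "conformer_ensemble")
  status <- "ok"
  log <- c(log, sprintf("STATUS %s time=%.2fs n_conf=%d", status, elapsed(),
                        length(confs)))
  list(ensemble = ens,
       report = list(status = status, time = elapsed(),
                     n_conformers = length(confs), log = log))
}

#' Generate ensembles for a batch of compounds
#'
#' Every input yields exactly one report record; per-compound failures
#' never abort the batch. The per-compound seed is `settings$seed`
#' offset by the batch position, so single-compound runs are reproducible
#' independently of batch context.
#'
#' @param compounds list of `mol_graph` objects.
#' @param settings a [generation_settings()].
#' @return List `ensembles` (NULL entries for failures) and `reports`.
#' @export
generate_batch <- function(compounds, settings = generation_settings()) {
  lib <- fragment_library(settings$frag_lib_path)
  ensembles <- vector("list", length(compounds))
  reports <- vector("list", length(compounds))
  for (k in seq_along(compounds)) {
    s <- settings
    s$seed <- settings$seed + k - 1L
    res <- try(generate_conformers(compounds[[k]], s, lib = lib),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      res <- list(ensemble = NULL,
                  report = list(status = "failed:internal", time = 0,
                                n_conformers = 0L,
                                log = attr(res, "condition")$message))
    }
    ensembles[[k]] <- res$ensemble
    reports[[k]] <- res$report
  }
  list(ensembles = ensembles, reports = reports, frag_lib = lib)
}
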