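# Stochastic conformer sampling: iterative random-conformer generation
# with an adaptive energy window, energy-based duplicate removal and
# convergence detection.

#' Settings for stochastic sampling
#'
#' @param max_samples maximum number of generation cycles (default 2000).
#' @param check_period convergence check interval in cycles (default 100).
#' @param dup_window energy difference below which two conformers are
#'   considered duplicates (kcal/mol, default 0.01).
#' @param energy_window maximum energy above the current minimum for
#'   ensemble membership (kcal/mol; 20 is the macrocycle default).
#' @param time_budget wall-clock budget in seconds (0 = unlimited).
#' @param max_trials per-conformer DG retry cap.
#' @return A `stochastic_settings` list.
#' @export
stochastic_settings <- function(max_samples = 2000L, check_period = 100L,
                                dup_window = 0.01, energy_window = 20,
                                time_budget = 0, max_trials = 10L) {
  stopifnot(max_samples > 0, check_period > 0, dup_window > 0,
            energy_window > 0, time_budget >= 0)
  structure(list(max_samples = as.integer(max_samples),
                 check_period = as.integer(check_period),
                 dup_window = dup_window, energy_window = energy_window,
                 time_budget = time_budget, max_trials = as.integer(max_trials)),
            class = "stochastic_settings")
}

#' Remove energy-duplicate conformers
#'
#' Among any cluster of conformers pairwise within the window, one
#' survivor is kept (the lowest energy; ties by insertion order). The
#' result is sorted by ascending energy.
#'
#' @param conformers list of conformers (each with `$energy`).
#' @param window duplicate energy window (kcal/mol).
#' @return Filtered, energy-sorted list.
#' @export
remove_energy_duplicates <- function(conformers, window = 0.01) {
  if (!length(conformers)) return(conformers)
  e <- vapply(conformers, function(c_) c_$energy, 0)
  ord <- order(e)  # stable: preserves insertion order among exact ties
  out <- list()
  last_e <- -Inf
  for (k in ord) {
    if (e[k] - last_e > window) {
      out[[length(out) + 1L]] <- conformers[[k]]
      last_e <- e[k]
    }
  }
  out
}

#' Stochastic conformer sampling loop
#'
#' Random conformers are generated iteratively until the sample cap is
#' reached, the time budget is exhausted, or sampling has converged (the
#' duplicate-free ensemble size did not increase over one check period).
#' Newly generated conformers enter the working ensemble only when within
#' the adaptive energy window above the current minimum; a final pass
#' discards members left above the (possibly lowered) window.
#'
#' @param mol preprocessed connected `mol_graph`.
#' @param param `mmff_param`.
#' @param settings a [stochastic_settings()] object.
#' @param macrocyclic macrocycle initialisation (passed to the DG stage).
#' @return List: `conformers` (energy-sorted, duplicate-free), `cycles`,
#'   `converged`, `ok` (FALSE if no conformer could be generated).
#' @export
stochastic_sample <- function(mol, param, settings = stochastic_settings(),
                              macrocyclic = TRUE) {
  td <- topological_distances(mol)
  bounds <- build_distance_bounds(mol, param, td)
  volumes <- build_volume_constraints(mol, bounds$atoms)
  ensemble <- list()
  e_min <- Inf
  last_size <- 0L
  converged <- FALSE
  t0 <- Sys.time()
  cycle <- 0L
  while (cycle < settings$max_samples) {
    cycle <- cycle + 1L
    g <- generate_random_conformer(mol, param, td, macrocyclic = macrocyclic,
                                   max_trials = settings$max_trials,
                                   stop_criterion = "energy_delta",
                                   threshold = 0.001,
                                   bounds = bounds, volumes = volumes)
    if (g$ok) {
      if (g$energy <= e_min + settings$energy_window) {
        ensemble[[length(ensemble) + 1L]] <-
          list(coords = g$coords, energy = g$energy)
        if (g$energy < e_min) e_min <- g$energy
      }
    }
    if (cycle %% settings$check_period == 0L) {
      ensemble <- remove_energy_duplicates(ensemble, settings$dup_window)
      if (length(ensemble) <= last_size && length(ensemble) > 0L) {
        converged <- TRUE
        break
      }
      last_size <- length(ensemble)
    }
    if (settings$time_budget > 0 &&
        as.numeric(Sys.time() - t0, units = "secs") > settings$time_budget) {
      break
    }
  }
  ensemble <- remove_energy_duplicates(ensemble, settings$dup_window)
  if (length(ensemble)) {
    e_min <- ensemble[[1]]$energy
    keep <- vapply(ensemble, function(c_) {
      c_$energy <= e_min + settings$energy_window
    }, TRUE)
    ensemble <- ensemble[keep]
  }
  list(conformers = ensemble, cycles = cycle, converged = converged,
       ok = length(ensemble) > 0L)
}
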