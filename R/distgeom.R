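# Random conformer generation by distance geometry: constraint
# construction, penalty-minimisation embedding, hydrogen placement, BFGS
# energy refinement and stereo validation with bounded retries.

# Covalent radii (Angstrom), single published table (Cordero et al. 2008),
# used for the lower distance bound of topologically remote pairs.
COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                    F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                    Se = 1.20, Br = 1.20, I = 1.39)

covalent_radius <- function(el) {
  r <- COVALENT_RADII[el]
  r[is.na(r)] <- 1.2
  unname(r)
}

#' Build distance bounds for DG embedding
#'
#' Bound construction by topological distance class: bonded pairs are fixed
#' at the MMFF94 reference bond length; geminal pairs at the law-of-cosines
#' distance from the two reference lengths and the equilibrium angle;
#' vicinal pairs range from the cis (coplanar) to the trans (anti-coplanar)
#' distance unless the central bond is a configured double bond, in which
#' case the matching arrangement's distance is fixed; remoter pairs get a
#' lower bound of the covalent-radius sum plus a 1.5 Angstrom safety
#' spacing and a shared upper bound equal to the total sum of all MMFF94
#' bond lengths.
#'
#' @param mol preprocessed, connected `mol_graph`.
#' @param param `mmff_param` for the molecule.
#' @param td topological distance matrix.
#' @param atoms indices of the atoms to embed (default: heavy atoms plus
#'   hydrogens bonded to defined stereocentres).
#' @return List: `pairs` (matrix i, j, lower, upper over embedded atoms in
#'   molecule indexing) and `atoms` (the embedded subset).
#' @export
build_distance_bounds <- function(mol, param, td, atoms = NULL) {
  stopifnot(isTRUE(param$ok))
  if (is.null(atoms)) atoms <- embedded_atom_set(mol)
  n <- length(atoms)
  # reference bond lengths / angles keyed for O(1) lookup
  r0 <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(param$bonds))) {
    assign(bond_key(param$bonds[r, 1], param$bonds[r, 2]), param$bonds[r, 4],
           envir = r0)
  }
  th0 <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(param$angles))) {
    key <- paste(param$angles[r, 1], param$angles[r, 2], param$angles[r, 3])
    assign(key, param$angles[r, 5], envir = th0)
    key2 <- paste(param$angles[r, 3], param$angles[r, 2], param$angles[r, 1])
    assign(key2, param$angles[r, 5], envir = th0)
  }
  get_r0 <- function(i, j) {
    k <- bond_key(i, j)
    if (!exists(k, envir = r0)) return(NA_real_)
    get(k, envir = r0)
  }
  get_th0 <- function(i, j, k) {
    key <- paste(i, j, k)
    if (!exists(key, envir = th0)) return(109.471)
    get(key, envir = th0)
  }
  adj <- adjacency(mol)
  upper_global <- sum(param$bonds[, 4])
  el <- mol$atoms$element
  # configured double bonds: fixed vicinal distances
  sb <- mol$stereo_bonds
  pairs <- matrix(0, 0, 4)
  rows <- vector("list", n * (n - 1) / 2)
  cnt <- 0L
  for (ai in seq_len(n - 1)) {
    for (bi in (ai + 1):n) {
      i <- atoms[ai]; j <- atoms[bi]
      t <- td[i, j]
      if (t == 1L) {
        d <- get_r0(i, j)
        if (is.na(d)) next
        lo <- d; hi <- d
      } else if (t == 2L) {
        mid <- intersect(adj[[i]], adj[[j]])[1]
        r1 <- get_r0(i, mid); r2 <- get_r0(mid, j)
        ang <- get_th0(i, mid, j) * pi / 180
        d <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(ang))
        lo <- d; hi <- d
      } else if (t == 3L) {
        # find the central bond of one shortest path i - x - y - j
        path <- NULL
        for (x in intersect(adj[[i]], which(td[, j] == 2L))) {
          ys <- intersect(adj[[x]], adj[[j]])
          ys <- ys[ys != i]
          if (length(ys)) { path <- c(i, x, ys[1], j); break }
        }
        if (is.null(path)) next
        dcis <- vicinal_distance(path, get_r0, get_th0, cis = TRUE)
        dtrans <- vicinal_distance(path, get_r0, get_th0, cis = FALSE)
        cfg <- NA_character_
        if (nrow(sb)) {
          hit <- which((sb$a == path[2] & sb$b == path[3]) |
                       (sb$a == path[3] & sb$b == path[2]))
          if (length(hit)) {
            h <- hit[1]
            # cis w.r.t. this atom pair iff both match / both differ from refs
            same_i <- (sb$a[h] == path[2] && sb$ref_a[h] == i) ||
                      (sb$b[h] == path[2] && sb$ref_b[h] == i)
            same_j <- (sb$a[h] == path[3] && sb$ref_a[h] == j) ||
                      (sb$b[h] == path[3] && sb$ref_b[h] == j)
            cfg <- if (same_i == same_j) sb$config[h]
                   else if (sb$config[h] == "cis") "trans" else "cis"
          }
        }
        if (!is.na(cfg)) {
          d <- if (cfg == "cis") dcis else dtrans
          lo <- d; hi <- d
        } else {
          lo <- min(dcis, dtrans); hi <- max(dcis, dtrans)
        }
      } else {
        lo <- covalent_radius(el[i]) + covalent_radius(el[j]) + 1.5
        hi <- upper_global
      }
      cnt <- cnt + 1L
      rows[[cnt]] <- c(i, j, lo, hi)
    }
  }
  pairs <- if (cnt) do.call(rbind, rows[seq_len(cnt)]) else matrix(0, 0, 4)
  list(pairs = pairs, atoms = atoms)
}

# distance between atoms 1 and 4 of a 4-atom path at dihedral 0 (cis) or
# 180 (trans), from reference lengths and equilibrium angles
vicinal_distance <- function(path, get_r0, get_th0, cis) {
  i <- path[1]; x <- path[2]; y <- path[3]; j <- path[4]
  r1 <- get_r0(i, x); r2 <- get_r0(x, y); r3 <- get_r0(y, j)
  a1 <- get_th0(i, x, y) * pi / 180
  a2 <- get_th0(x, y, j) * pi / 180
  # x at origin, y along +x; i and j at the equilibrium angles, j on the
  # same side as i for the coplanar (cis) arrangement
  pi_ <- c(r1 * cos(a1), r1 * sin(a1), 0)
  sgn <- if (cis) 1 else -1
  pj <- c(r2 - r3 * cos(a2), sgn * r3 * sin(a2), 0)
  sqrt(sum((pi_ - pj)^2))
}

# atoms that take part in the embedding: heavy atoms + hydrogens bonded to
# defined stereocentres
embedded_atom_set <- function(mol) {
  heavy <- which(!is_hydrogen(mol))
  extra <- integer(0)
  if (nrow(mol$stereo_atoms)) {
    for (r in seq_len(nrow(mol$stereo_atoms))) {
      nb <- c(mol$stereo_atoms$n1[r], mol$stereo_atoms$n2[r],
              mol$stereo_atoms$n3[r], mol$stereo_atoms$n4[r])
      extra <- c(extra, nb[is_hydrogen(mol)[nb]])
    }
  }
  sort(unique(c(heavy, extra)))
}

#' Build signed-volume constraints
#'
#' One signed-volume range per defined tetrahedral stereocentre (limits
#' 0.5 to 1000 cubic Angstrom, sign from the configured parity) and
#' zero-volume constraints for planar groups: sp2/aromatic atoms and amide
#' nitrogens with three neighbours, and the substituent quadruples across
#' amide, aromatic and double bonds.
#'
#' @param mol preprocessed `mol_graph`.
#' @param atoms atom subset to restrict constraints to (all atoms by default; the DG embedder passes its embedded subset).
#' @return Matrix with columns i, j, k, l, lo, hi (the signed volume is the
#'   triple product of the first three atoms' positions relative to the
#'   fourth).
#' @export
build_volume_constraints <- function(mol, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(mol))
  inset <- logical(n_atoms(mol))
  inset[atoms] <- TRUE
  rows <- list()
  sa <- mol$stereo_atoms
  for (r in seq_len(nrow(sa))) {
    nb <- c(sa$n1[r], sa$n2[r], sa$n3[r], sa$n4[r])
    if (!all(inset[nb])) next
    if (sa$parity[r] > 0) {
      rows[[length(rows) + 1L]] <- c(nb, 0.5, 1000)
    } else {
      rows[[length(rows) + 1L]] <- c(nb, -1000, -0.5)
    }
  }
  adj <- adjacency(mol)
  planar_center <- function(a) {
    if (mol$atoms$hyb[a] == "sp2" || mol$atoms$aromatic[a]) return(TRUE)
    # amide nitrogen: N single-bonded to a carbonyl carbon
    if (mol$atoms$element[a] == "N") {
      for (c_ in adj[[a]]) {
        if (mol$atoms$element[c_] != "C") next
        for (o in adj[[c_]]) {
          b <- find_bond(mol, c_, o)
          if (mol$atoms$element[o] == "O" && mol$bonds$order[b] == 2L) return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- n_atoms(mol)
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    if (length(nb) == 3 && inset[a] && all(inset[nb]) && planar_center(a)) {
      rows[[length(rows) + 1L]] <- c(nb, a, 0, 0)
    }
  }
  # coplanarity of substituents across double/aromatic/amide bonds
  for (r in seq_len(nrow(mol$bonds))) {
    dbl <- mol$bonds$order[r] == 2L || isTRUE(mol$bonds$aromatic[r])
    a <- mol$bonds$i[r]; b <- mol$bonds$j[r]
    amide <- FALSE
    if (!dbl && mol$bonds$order[r] == 1L) {
      ca <- if (mol$atoms$element[a] == "C" && mol$atoms$element[b] == "N") a
            else if (mol$atoms$element[b] == "C" && mol$atoms$element[a] == "N") b
            else NA
      if (!is.na(ca)) {
        for (o in adj[[ca]]) {
          bb <- find_bond(mol, ca, o)
          if (mol$atoms$element[o] == "O" && mol$bonds$order[bb] == 2L) amide <- TRUE
        }
      }
    }
    if (!dbl && !amide) next
    for (x in setdiff(adj[[a]], b)) {
      for (y in setdiff(adj[[b]], a)) {
        if (all(inset[c(x, a, b, y)])) {
          rows[[length(rows) + 1L]] <- c(x, a, b, y, 0, 0)
        }
      }
    }
  }
  if (!length(rows)) return(matrix(0, 0, 6))
  do.call(rbind, rows)
}

#' Embed coordinates satisfying distance and volume constraints
#'
#' Atom positions are initialised uniformly at random in a cube whose edge
#' is the embedded atom count times a structure-type-specific factor, then
#' refined by BFGS minimisation of a smooth penalty (sum of squared bound
#' and volume-range violations) until the mean squared violation falls
#' below the tolerance.
#'
#' @param bounds result of [build_distance_bounds()].
#' @param volumes matrix from [build_volume_constraints()].
#' @param init_factor box edge per atom (0.25 for small molecules, 0.5 for
#'   macrocycles).
#' @param tol mean squared constraint violation accepted (Angstrom^2; the default admits about 0.045 Angstrom RMS residual per constraint, loose enough for slightly inconsistent bound sets around hypervalent centres, far below any stereo-flip signal).
#' @param maxit BFGS iteration cap.
#' @return List `coords` (matrix over the embedded subset, molecule
#'   indexing preserved in rownames), `ok`, `violation`.
#' @export
dg_embed <- function(bounds, volumes, init_factor = 0.25, tol = 2e-3,
                     maxit = 500L) {
  atoms <- bounds$atoms
  n <- length(atoms)
  if (n == 1L || !nrow(bounds$pairs)) {
    coords <- matrix(0, n, 3)
    rownames(coords) <- atoms
    return(list(coords = coords, atoms = atoms, ok = TRUE, violation = 0))
  }
  box <- max(n * init_factor, 2)
  x0 <- runif(3 * n, 0, box)
  # remap constraint indices into the embedded subset
  map <- integer(max(atoms))
  map[atoms] <- seq_len(n)
  prs <- bounds$pairs
  prs[, 1] <- map[prs[, 1]]; prs[, 2] <- map[prs[, 2]]
  vols <- volumes
  if (nrow(vols)) for (c_ in 1:4) vols[, c_] <- map[vols[, c_]]
  fn <- function(x) cpp_dg_penalty(x, prs, vols, FALSE)$value
  gr <- function(x) cpp_dg_penalty(x, prs, vols, TRUE)$gradient
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  nc <- nrow(prs) + nrow(vols)
  viol <- res$value / max(nc, 1)
  coords <- matrix(res$par, ncol = 3, byrow = TRUE)  # atom-major layout
  rownames(coords) <- atoms
  list(coords = coords, atoms = atoms, ok = viol <= tol, violation = viol)
}

#' Place hydrogens at ideal geometry
#'
#' Fills in coordinates for hydrogens that were excluded from the
#' embedding, using the parent atom's hybridisation (tetrahedral, trigonal
#' or linear completion) and the MMFF94 reference X-H bond length. Atoms
#' without positioned heavy neighbours (water, ammonia) use the MMFF94
#' equilibrium H-X-H angle.
#'
#' @param mol `mol_graph`.
#' @param param `mmff_param` (for reference lengths/angles).
#' @param coords N x 3 matrix with embedded rows filled, NA elsewhere.
#' @return Complete N x 3 coordinate matrix.
#' @export
place_hydrogens <- function(mol, param, coords) {
  adj <- adjacency(mol)
  n <- n_atoms(mol)
  r0 <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(param$bonds))) {
    assign(bond_key(param$bonds[r, 1], param$bonds[r, 2]), param$bonds[r, 4],
           envir = r0)
  }
  get_r0 <- function(i, j) {
    k <- bond_key(i, j)
    if (exists(k, envir = r0)) get(k, envir = r0) else 1.09
  }
  th0 <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(param$angles))) {
    assign(paste(param$angles[r, 1], param$angles[r, 2], param$angles[r, 3]),
           param$angles[r, 5], envir = th0)
  }
  unplaced <- which(is.na(coords[, 1]))
  for (p in seq_len(n)) {
    hs <- intersect(adj[[p]], unplaced)
    if (!length(hs)) next
    placed <- setdiff(adj[[p]], hs)
    placed <- placed[!is.na(coords[placed, 1])]
    hyb <- mol$atoms$hyb[p]
    orig <- coords[p, ]
    dirs <- ideal_directions(length(placed), length(hs), hyb,
                             if (length(placed))
                               sweep(coords[placed, , drop = FALSE], 2, orig)
                             else NULL,
                             hxh_angle(hs, p, th0))
    for (t in seq_along(hs)) {
      h <- hs[t]
      coords[h, ] <- orig + dirs[t, ] * get_r0(p, h)
    }
  }
  coords
}

hxh_angle <- function(hs, p, th0) {
  if (length(hs) < 2) return(109.471)
  key <- paste(hs[1], p, hs[2])
  key2 <- paste(hs[2], p, hs[1])
  if (exists(key, envir = th0)) return(get(key, envir = th0))
  if (exists(key2, envir = th0)) return(get(key2, envir = th0))
  109.471
}

# Unit direction vectors for m new substituents given k placed neighbour
# displacement vectors (rows of `placed`, relative to the centre).
ideal_directions <- function(k, m, hyb, placed, angle0 = 109.471) {
  unit <- function(v) v / max(sqrt(sum(v^2)), 1e-12)
  perp <- function(v) {
    w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    unit(pracma_cross(v, w))
  }
  if (k == 0) {
    # isolated centre: canonical geometry
    a <- angle0 * pi / 180
    base <- switch(as.character(min(m, 4)),
      "1" = matrix(c(1, 0, 0), 1),
      "2" = rbind(c(cos(a / 2), sin(a / 2), 0), c(cos(a / 2), -sin(a / 2), 0)),
      "3" = rbind(c(1, 0, 0),
                  c(cos(a), sin(a), 0),
                  unit(c(cos(a), cos(a) * (1 - cos(a)) / sin(a),
                         sqrt(max(0, 1 - cos(a)^2 - (cos(a) * (1 - cos(a)) / sin(a))^2))))),
      "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3))
    return(base[seq_len(m), , drop = FALSE])
  }
  u <- lapply(seq_len(k), function(t) unit(placed[t, ]))
  if (hyb == "sp" || (k == 1 && m == 1 && hyb == "other")) {
    return(matrix(-u[[1]], 1))
  }
  if (k >= 3) {
    # complete the tetrahedron opposite the placed-neighbour centroid
    s <- -unit(Reduce(`+`, u))
    return(matrix(s, m, 3, byrow = TRUE))
  }
  if (k == 2) {
    bis <- -unit(u[[1]] + u[[2]])
    if (hyb == "sp2") return(matrix(bis, m, 3, byrow = TRUE))
    # sp3: the two completion directions straddle the placed plane
    nrm <- unit(pracma_cross(u[[1]], u[[2]]))
    half <- 0.5 * 109.471 * pi / 180
    cand <- rbind(unit(bis * cos(half) + nrm * sin(half)),
                  unit(bis * cos(half) - nrm * sin(half)))
    return(cand[seq_len(min(m, 2)), , drop = FALSE])
  }
  # k == 1: fan of directions at the hybridisation angle around the axis
  v <- u[[1]]
  pv <- perp(v)
  a <- (if (hyb == "sp2") 120 else 109.471) * pi / 180
  w <- unit(pracma_cross(v, pv))
  slots <- if (hyb == "sp2") 2L else 3L
  out <- matrix(0, m, 3)
  for (t in seq_len(m)) {
    phi <- 2 * pi * (t - 1) / slots
    out[t, ] <- unit(cos(pi - a) * v +
                     sin(pi - a) * (cos(phi) * pv + sin(phi) * w))
  }
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Check stereocentre and double-bond configurations against coordinates
#'
#' Recomputes tetrahedral parities (sign of the neighbour signed volume)
#' and double-bond reference sides from the coordinates and compares them
#' with the declared descriptors; unspecified centres are skipped.
#'
#' @param mol `mol_graph` with stereo assigned.
#' @param coords N x 3 coordinates (embedded stereocentre neighbourhoods
#'   must be filled).
#' @param specified_only check only descriptors read from input (not
#'   default-assigned double-bond geometry).
#' @return Logical vector (one per checked descriptor, atoms first);
#'   attribute `detail` carries a data.frame.
#' @export
check_stereo <- function(mol, coords, specified_only = FALSE) {
  res <- logical(0)
  what <- character(0)
  sa <- mol$stereo_atoms
  for (r in seq_len(nrow(sa))) {
    nb <- c(sa$n1[r], sa$n2[r], sa$n3[r], sa$n4[r])
    if (any(is.na(coords[nb, 1]))) { res <- c(res, NA); what <- c(what, "atom"); next }
    v <- signed_volume(coords[nb[1], ], coords[nb[2], ], coords[nb[3], ],
                       coords[nb[4], ])
    res <- c(res, sign(v) == sa$parity[r])
    what <- c(what, "atom")
  }
  sb <- mol$stereo_bonds
  for (r in seq_len(nrow(sb))) {
    if (specified_only && !isTRUE(sb$specified[r])) next
    a <- sb$a[r]; b <- sb$b[r]
    axis <- coords[b, ] - coords[a, ]
    axis <- axis / max(sqrt(sum(axis^2)), 1e-12)
    pa <- coords[sb$ref_a[r], ] - coords[a, ]
    pb <- coords[sb$ref_b[r], ] - coords[b, ]
    pa <- pa - sum(pa * axis) * axis
    pb <- pb - sum(pb * axis) * axis
    same <- sum(pa * pb) > 0
    res <- c(res, if (sb$config[r] == "cis") same else !same)
    what <- c(what, "bond")
  }
  attr(res, "what") <- what
  res
}

signed_volume <- function(p1, p2, p3, p4) {
  sum((p1 - p4) * pracma_cross(p2 - p4, p3 - p4))
}

#' Refine coordinates by BFGS energy minimisation
#'
#' Iterative MMFF94 energy minimisation with a caller-selected stopping
#' criterion: the run stops when the gradient norm or the energy change
#' between outer iterations drops below the threshold, or at the iteration
#' cap. Accepted iterations never increase the energy.
#'
#' @param param `mmff_param`.
#' @param coords starting N x 3 coordinates.
#' @param stop_criterion "gradient_norm" or "energy_delta".
#' @param threshold stop threshold (kcal/mol/A for the gradient norm, i.e.
#'   the RMS gradient; kcal/mol for the energy change).
#' @param maxit outer iteration cap.
#' @return List `coords`, `energy`, `converged`, `niter`.
#' @export
refine_conformer <- function(param, coords,
                             stop_criterion = c("gradient_norm", "energy_delta"),
                             threshold = 0.1, maxit = 200L) {
  stop_criterion <- match.arg(stop_criterion)
  n <- nrow(coords)
  fn <- function(x) {
    e <- cpp_mmff_energy(matrix(x, ncol = 3, byrow = TRUE), param$bonds,
                         param$angles, param$sb, param$oop, param$tors,
                         param$nb, FALSE)$total
    if (!is.finite(e)) 1e10 else e
  }
  gr <- function(x) {
    g <- cpp_mmff_energy(matrix(x, ncol = 3, byrow = TRUE), param$bonds,
                         param$angles, param$sb, param$oop, param$tors,
                         param$nb, TRUE)$gradient
    g[!is.finite(g)] <- 0
    as.numeric(t(g))
  }
  x <- as.numeric(t(coords))
  e_prev <- fn(x)
  converged <- FALSE
  iters <- 0L
  chunk <- 40L
  while (iters < maxit) {
    res <- try(stats::optim(x, fn, gr, method = "L-BFGS-B",
                            control = list(maxit = chunk, factr = 1)),
               silent = TRUE)
    if (inherits(res, "try-error")) break
    iters <- iters + chunk
    if (res$value <= e_prev) x <- res$par
    e_new <- min(res$value, e_prev)
    gnorm <- sqrt(mean(gr(x)^2))
    if (stop_criterion == "gradient_norm" && gnorm <= threshold) {
      converged <- TRUE; e_prev <- e_new; break
    }
    if (stop_criterion == "energy_delta" && abs(e_prev - e_new) <= threshold) {
      converged <- TRUE; e_prev <- e_new; break
    }
    if (abs(e_prev - e_new) < 1e-12 && res$convergence == 0) {
      converged <- TRUE; e_prev <- e_new; break
    }
    e_prev <- e_new
  }
  co <- matrix(x, ncol = 3, byrow = TRUE)
  if (!is.finite(e_prev)) {
    return(list(coords = co, energy = Inf, converged = FALSE, niter = iters))
  }
  list(coords = co, energy = e_prev, converged = converged, niter = iters)
}

#' Generate one random low-energy conformer
#'
#' The full random-generation workflow: random initialisation and penalty
#' embedding of the heavy atoms (plus stereocentre hydrogens), stereo
#' validation of the raw structure, ideal-geometry hydrogen placement,
#' BFGS energy refinement and a final stereo check. On any failure a new
#' attempt with fresh random positions is made, up to `max_trials`.
#'
#' @param mol preprocessed connected `mol_graph`.
#' @param param `mmff_param`.
#' @param td topological distance matrix (computed if NULL).
#' @param macrocyclic use the macrocycle initialisation factor (0.5/atom
#'   instead of 0.25/atom).
#' @param max_trials attempt cap (default 10).
#' @param stop_criterion,threshold refinement stop rule (see
#'   [refine_conformer()]).
#' @param bounds,volumes precomputed constraints (rebuilt if NULL).
#' @return List `coords`, `energy`, `ok`, `trials`, `failure`
#'   ("embed", "stereo", "refine" or NA).
#' @export
generate_random_conformer <- function(mol, param, td = NULL,
                                      macrocyclic = FALSE, max_trials = 10L,
                                      stop_criterion = "energy_delta",
                                      threshold = 0.001,
                                      bounds = NULL, volumes = NULL) {
  if (is.null(td)) td <- topological_distances(mol)
  if (is.null(bounds)) bounds <- build_distance_bounds(mol, param, td)
  if (is.null(volumes)) volumes <- build_volume_constraints(mol, bounds$atoms)
  init_factor <- if (macrocyclic) 0.5 else 0.25
  failure <- NA_character_
  for (trial in seq_len(max_trials)) {
    emb <- dg_embed(bounds, volumes, init_factor = init_factor)
    if (!emb$ok) { failure <- "embed"; next }
    coords <- matrix(NA_real_, n_atoms(mol), 3)
    coords[emb$atoms, ] <- emb$coords
    chk <- check_stereo(mol, coords)
    chk_atoms <- chk[attr(chk, "what") == "atom"]
    if (length(chk_atoms) && !all(chk_atoms, na.rm = TRUE)) {
      failure <- "stereo"; next
    }
    coords <- place_hydrogens(mol, param, coords)
    ref <- refine_conformer(param, coords, stop_criterion, threshold)
    if (!is.finite(ref$energy)) { failure <- "refine"; next }
    chk2 <- check_stereo(mol, ref$coords)
    if (length(chk2) && !all(chk2, na.rm = TRUE)) { failure <- "stereo"; next }
    return(list(coords = ref$coords, energy = ref$energy, ok = TRUE,
                trials = trial, failure = NA_character_))
  }
  list(coords = NULL, energy = NA_real_, ok = FALSE, trials = max_trials,
       failure = if (is.na(failure)) "embed" else failure)
}
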