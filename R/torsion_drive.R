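# Fragment-tree torsion driving: tree construction over the link bonds,
# static assignment of force-field terms to tree nodes (so each
# parametrized interaction is evaluated exactly once per generated
# conformer), rigid-body child alignment at rotor bonds, and the driving
# loop over energy-ordered FCCs with early pruning.

#' Build the fragment tree
#'
#' Leaves are fragments; every internal node references one link bond and
#' joins the two subtrees containing its atoms. Trees are merged greedily,
#' attaching the smallest subtrees first (ties by the link bond's atom
#' indices), which keeps intermediate conformer pools small.
#'
#' @param mol `mol_graph`.
#' @param frag result of [fragment_molecule()].
#' @return List `nodes` (each with `type`, `atoms`, and for internal nodes
#'   `left`, `right`, `bond`, `link_row`) and `root` (node index).
#' @export
build_fragment_tree <- function(mol, frag) {
  nf <- length(frag$fragments)
  nodes <- lapply(seq_len(nf), function(k) {
    list(type = "leaf", frag = k, atoms = frag$fragments[[k]])
  })
  tree_of <- seq_len(nf)            # fragment -> current tree root node
  remaining <- seq_len(nrow(frag$link_bonds))
  while (length(remaining)) {
    sizes <- vapply(remaining, function(r) {
      ta <- tree_of[frag$link_bonds$frag_a[r]]
      tb <- tree_of[frag$link_bonds$frag_b[r]]
      if (ta == tb) return(NA_integer_)
      length(nodes[[ta]]$atoms) + length(nodes[[tb]]$atoms)
    }, 0L)
    ok <- which(!is.na(sizes))
    stopifnot(length(ok) > 0)
    keys_a <- pmin(frag$link_bonds$a[remaining], frag$link_bonds$b[remaining])
    keys_b <- pmax(frag$link_bonds$a[remaining], frag$link_bonds$b[remaining])
    pick <- ok[order(sizes[ok], keys_a[ok], keys_b[ok])][1]
    r <- remaining[pick]
    remaining <- remaining[-pick]
    a <- frag$link_bonds$a[r]; b <- frag$link_bonds$b[r]
    ta <- tree_of[frag$link_bonds$frag_a[r]]
    tb <- tree_of[frag$link_bonds$frag_b[r]]
    # orient so that atom `a` lies in the left child
    if (a %in% nodes[[tb]]$atoms) { tmp <- ta; ta <- tb; tb <- tmp }
    new_node <- list(type = "node", left = ta, right = tb, bond = c(a, b),
                     link_row = r,
                     atoms = sort(c(nodes[[ta]]$atoms, nodes[[tb]]$atoms)))
    nodes[[length(nodes) + 1L]] <- new_node
    tree_of[tree_of %in% c(ta, tb)] <- length(nodes)
    # tree_of indexes by fragment; update all fragments in either subtree
    for (k in seq_len(nf)) {
      if (tree_of[k] %in% c(ta, tb)) tree_of[k] <- length(nodes)
    }
  }
  list(nodes = nodes, root = tree_of[1])
}

# Assign every force-field term to the unique tree node where all its
# atoms are first jointly present. Returns per-node lists of row indices
# into the param matrices.
assign_terms_to_tree <- function(tree, param, natoms) {
  nn <- length(tree$nodes)
  member <- matrix(FALSE, nn, natoms)
  for (k in seq_len(nn)) member[k, tree$nodes[[k]]$atoms] <- TRUE
  assign_cat <- function(mat, idx_cols) {
    res <- replicate(nn, integer(0), simplify = FALSE)
    for (r in seq_len(nrow(mat))) {
      at <- mat[r, idx_cols]
      node <- tree$root
      repeat {
        nd <- tree$nodes[[node]]
        if (nd$type == "leaf") break
        if (all(member[nd$left, at])) { node <- nd$left; next }
        if (all(member[nd$right, at])) { node <- nd$right; next }
        break
      }
      res[[node]] <- c(res[[node]], r)
    }
    res
  }
  list(bonds = assign_cat(param$bonds, 1:2),
       angles = assign_cat(param$angles, 1:3),
       sb = assign_cat(param$sb, 1:3),
       oop = assign_cat(param$oop, 1:4),
       tors = assign_cat(param$tors, 1:4),
       nb = assign_cat(param$nb, 1:2))
}

node_param_slice <- function(param, terms, node) {
  list(bonds = param$bonds[terms$bonds[[node]], , drop = FALSE],
       angles = param$angles[terms$angles[[node]], , drop = FALSE],
       sb = param$sb[terms$sb[[node]], , drop = FALSE],
       oop = param$oop[terms$oop[[node]], , drop = FALSE],
       tors = param$tors[terms$tors[[node]], , drop = FALSE],
       nb = param$nb[terms$nb[[node]], , drop = FALSE])
}

eval_slice <- function(slice, coords) {
  cpp_mmff_energy(coords, slice$bonds, slice$angles, slice$sb, slice$oop,
                  slice$tors, slice$nb, FALSE)$total
}

#' Measure a signed dihedral angle
#'
#' @param coords N x 3 matrix.
#' @param i,j,k,l atom indices (rotation about j-k).
#' @return Angle in degrees in [0, 360).
#' @export
dihedral_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  y <- sum(pracma_cross(n1, n2) * b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  (atan2(y, x) * 180 / pi) %% 360
}

rotation_between <- function(u, v) {
  # proper rotation taking unit vector u to unit vector v
  c_ <- sum(u * v)
  ax <- pracma_cross(u, v)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- pracma_cross(u, p)
    ax <- ax / sqrt(sum(ax^2))
    return(rotation_about(ax, pi))
  }
  ax <- ax / s
  rotation_about(ax, atan2(s, c_))
}

rotation_about <- function(axis, theta) {
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c_ <- cos(theta); s <- sin(theta); t <- 1 - c_
  rbind(c(t * x * x + c_, t * x * y - s * z, t * x * z + s * y),
        c(t * x * y + s * z, t * y * y + c_, t * y * z - s * x),
        c(t * x * z - s * y, t * y * z + s * x, t * z * z + c_))
}

# A node conformer: full-size N x 3 coordinate matrix (NA outside the
# subtree), cap matrix (columns a, b, x, y, z: cap direction marker for the
# still-open cut bond a->b), and the accumulated subtree energy.

leaf_conformer <- function(mol, frag_conf, capped, frag_atoms, natoms) {
  pidx <- attr(capped, "parent_index")
  caps <- attr(capped, "caps")
  coords <- matrix(NA_real_, natoms, 3)
  coords[pidx, ] <- frag_conf$coords[seq_along(pidx), , drop = FALSE]
  capm <- matrix(0, nrow(caps), 5)
  for (r in seq_len(nrow(caps))) {
    capm[r, ] <- c(caps$a[r], caps$b[r], frag_conf$coords[caps$local[r], ])
  }
  list(coords = coords, caps = capm)
}

dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  y <- sum(pracma_cross(n1, n2) * b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  (atan2(y, x) * 180 / pi) %% 360
}

# resolve a torsion reference point from a node conformer: either a real
# atom or the cap marking a still-open cut bond
ref_point <- function(conf, spec) {
  if (!is.na(spec$atom)) return(conf$coords[spec$atom, ])
  crow <- which(conf$caps[, 1] == spec$cap[1] & conf$caps[, 2] == spec$cap[2])
  conf$caps[crow[1], 3:5]
}

# Rigid-body merge of two node conformers at rotor bond (a, b) with target
# dihedral theta over the reference points (x, a, b, y).
merge_node_conformers <- function(left, right, a, b, r0, x, y, theta) {
  ca <- left$coords[a, ]
  crow <- which(left$caps[, 1] == a & left$caps[, 2] == b)
  dir <- left$caps[crow[1], 3:5] - ca
  dir <- dir / sqrt(sum(dir^2))
  target_b <- ca + r0 * dir
  cb <- right$coords[b, ]
  crow2 <- which(right$caps[, 1] == b & right$caps[, 2] == a)
  dirb <- right$caps[crow2[1], 3:5] - cb
  dirb <- dirb / sqrt(sum(dirb^2))
  R1 <- rotation_between(dirb, -dir)
  rc <- right$coords
  ok <- !is.na(rc[, 1])
  rc[ok, ] <- sweep(sweep(rc[ok, , drop = FALSE], 2, cb) %*% t(R1), 2,
                    target_b, `+`)
  rcaps <- right$caps
  if (nrow(rcaps)) {
    rcaps[, 3:5] <- sweep(sweep(rcaps[, 3:5, drop = FALSE], 2, cb) %*% t(R1),
                          2, target_b, `+`)
  }
  # set the dihedral by rotating the right side about the bond axis
  coords <- left$coords
  coords[ok, ] <- rc[ok, ]
  xp <- ref_point(left, x)
  tmp_right <- list(coords = rc, caps = rcaps)
  yp <- ref_point(tmp_right, y)
  cur <- dihedral_points(xp, ca, target_b, yp)
  delta <- (theta - cur) * pi / 180
  if (abs(delta) > 1e-10) {
    R2 <- rotation_about(dir, delta)
    piv <- target_b
    rc[ok, ] <- sweep(sweep(rc[ok, , drop = FALSE], 2, piv) %*% t(R2), 2,
                      piv, `+`)
    if (nrow(rcaps)) {
      rcaps[, 3:5] <- sweep(sweep(rcaps[, 3:5, drop = FALSE], 2, piv) %*% t(R2),
                            2, piv, `+`)
    }
    coords[ok, ] <- rc[ok, ]
  }
  caps <- rbind(left$caps[-crow, , drop = FALSE],
                rcaps[-crow2, , drop = FALSE])
  list(coords = coords, caps = caps)
}

#' Prepare torsion-driving state for a molecule
#'
#' Builds the fragment tree, assigns force-field terms to nodes, and
#' resolves the torsion angle list of every rotor bond (library lookup,
#' optional tolerance expansion, symmetry reduction, amide restriction).
#'
#' @param mol `mol_graph`.
#' @param param molecule-level `mmff_param` (with `smarts_matches` for the
#'   concatenated libraries).
#' @param frag result of [fragment_molecule()].
#' @param libs torsion libraries, highest precedence first.
#' @param tolerance_sampling expand angles by their first tolerance range.
#' @return List `tree`, `terms`, `node_info` (per internal node: angles,
#'   reference atoms, r0).
#' @export
prepare_torsion_drive <- function(mol, param, frag, libs,
                                  tolerance_sampling = FALSE) {
  tree <- build_fragment_tree(mol, frag)
  terms <- assign_terms_to_tree(tree, param, n_atoms(mol))
  cv <- morgan_connectivity(mol)
  heavy <- !is_hydrogen(mol)
  adj <- adjacency(mol)
  r0_lookup <- function(a, b) {
    for (r in seq_len(nrow(param$bonds))) {
      if ((param$bonds[r, 1] == a && param$bonds[r, 2] == b) ||
          (param$bonds[r, 1] == b && param$bonds[r, 2] == a)) {
        return(param$bonds[r, 4])
      }
    }
    1.52
  }
  node_info <- vector("list", length(tree$nodes))
  for (k in seq_along(tree$nodes)) {
    nd <- tree$nodes[[k]]
    if (nd$type != "node") next
    a <- nd$bond[1]; b <- nd$bond[2]
    rule <- match_torsion_rules(mol, c(a, b), libs,
                                param$smarts_matches %||% list())
    angles <- expand_tolerance_angles(rule, tolerance_sampling)
    if (isTRUE(frag$link_bonds$amide[nd$link_row])) {
      angles <- c(180, 0)
    }
    left_atoms <- tree$nodes[[nd$left]]$atoms
    right_atoms <- tree$nodes[[nd$right]]$atoms
    angles <- reduce_symmetric_angles(mol, c(a, b), left_atoms, right_atoms,
                                      angles)
    ref_pick <- function(center, other, side) {
      cand <- intersect(setdiff(adj[[center]], other), side)
      hv <- cand[heavy[cand]]
      pool <- if (length(hv)) hv else cand
      if (length(pool)) {
        return(list(atom = pool[order(-cv[pool], pool)][1], cap = NULL))
      }
      # bare junction atom: reference the cap of another still-open cut
      # bond at this centre
      partners <- setdiff(adj[[center]], c(other, side))
      list(atom = NA_integer_,
           cap = c(center, partners[order(-cv[partners], partners)][1]))
    }
    x <- ref_pick(a, b, left_atoms)
    y <- ref_pick(b, a, right_atoms)
    node_info[[k]] <- list(angles = angles, x = x, y = y,
                           r0 = r0_lookup(a, b), rule = rule$rule)
  }
  list(tree = tree, terms = terms, node_info = node_info)
}

#' Torsion-drive a set of FCCs into candidate conformers
#'
#' The driving loop of the systematic sampler. FCCs are processed in
#' ascending combination energy; each initialises the fragment-tree
#' leaves, conformers are generated bottom-up at every internal node by
#' aligning child conformer pairs at the rotor bond for every assigned
#' dihedral angle, with incremental energy evaluation (child energies and
#' all subtree-internal terms are reused; only junction terms are
#' computed per candidate) and window pruning. Root conformers feed the
#' output working set with an adaptive minimum; the loop exits early when
#' the FCC energy exceeds the limit set by the best conformer so far or
#' when the working set reaches the pool cap.
#'
#' @param mol `mol_graph`.
#' @param param molecule `mmff_param`.
#' @param prep result of [prepare_torsion_drive()].
#' @param frag fragmentation result.
#' @param conf_sets per-fragment conformer lists.
#' @param fccs data.frame from [enumerate_fccs()].
#' @param window energy window (kcal/mol).
#' @param pool_cap node conformer pool cap (default 10000).
#' @param max_pool output working-set cap (default 10000).
#' @return List `conformers` (each `coords`, `energy`), `fccs_processed`,
#'   `ok`.
#' @export
drive_fccs <- function(mol, param, prep, frag, conf_sets, fccs,
                       window = 15, pool_cap = 10000L, max_pool = 10000L) {
  tree <- prep$tree
  nodes <- tree$nodes
  natoms <- n_atoms(mol)
  nfrag <- length(frag$fragments)
  capped_list <- attr(conf_sets, "capped")
  slices <- lapply(seq_along(nodes), function(k)
    node_param_slice(param, prep$terms, k))
  # topological evaluation order (children before parents)
  topo <- integer(0)
  visit <- function(k) {
    nd <- nodes[[k]]
    if (nd$type == "node") { visit(nd$left); visit(nd$right) }
    topo <<- c(topo, k)
  }
  visit(tree$root)
  working <- list()
  e_min_out <- Inf
  e_limit <- Inf
  processed <- 0L
  for (fi in seq_len(nrow(fccs))) {
    if (fccs$e_comb[fi] > e_limit) break
    if (length(working) >= max_pool) break
    processed <- processed + 1L
    store <- vector("list", length(nodes))
    failed <- FALSE
    for (k in topo) {
      nd <- nodes[[k]]
      if (nd$type == "leaf") {
        ci <- fccs[[paste0("i", nd$frag)]][fi]
        lc <- leaf_conformer(mol, conf_sets[[nd$frag]][[ci]],
                             capped_list[[nd$frag]],
                             frag$fragments[[nd$frag]], natoms)
        co <- lc$coords
        co[is.na(co)] <- 0
        lc$energy <- eval_slice(slices[[k]], co)
        store[[k]] <- list(lc)
        next
      }
      info <- prep$node_info[[k]]
      lefts <- store[[nd$left]]
      rights <- store[[nd$right]]
      out <- list()
      e_node_min <- Inf
      for (L in lefts) for (R in rights) for (th in info$angles) {
        mc <- merge_node_conformers(L, R, nd$bond[1], nd$bond[2], info$r0,
                                    info$x, info$y, th)
        co <- mc$coords
        co[is.na(co)] <- 0
        e <- L$energy + R$energy + eval_slice(slices[[k]], co)
        if (!is.finite(e)) next
        if (e > e_node_min + window) next
        if (e < e_node_min) e_node_min <- e
        mc$energy <- e
        out[[length(out) + 1L]] <- mc
      }
      if (!length(out)) { failed <- TRUE; break }
      es <- vapply(out, function(c_) c_$energy, 0)
      keep <- es <= e_node_min + window
      out <- out[keep][order(es[keep])]
      if (length(out) > pool_cap) out <- out[seq_len(pool_cap)]
      store[[k]] <- out
    }
    if (failed) next
    for (rc in store[[tree$root]]) {
      if (rc$energy > e_min_out + window) next
      working[[length(working) + 1L]] <-
        list(coords = rc$coords, energy = rc$energy)
      if (rc$energy < e_min_out) {
        e_min_out <- rc$energy
        e_limit <- fccs$e_comb[fi] + window
        keep <- vapply(working, function(w) {
          w$energy <= e_min_out + window
        }, TRUE)
        working <- working[keep]
      }
    }
  }
  list(conformers = working, fccs_processed = processed,
       ok = length(working) > 0L)
}

#' Systematic conformer sampling for one molecule
#'
#' Full systematic pipeline: fragmentation, per-fragment conformer
#' generation (library-backed), FCC enumeration, and fragment-tree
#' torsion driving.
#'
#' @param mol preprocessed connected `mol_graph`.
#' @param param molecule `mmff_param` (with SMARTS matches for `libs`).
#' @param frag_params `mmff_param` list for the capped fragments, parallel
#'   to the fragmentation's fragment list (see [prepare_systematic()]).
#' @param frag fragmentation result.
#' @param libs torsion libraries.
#' @param lib fragment conformer library.
#' @param window energy window (kcal/mol).
#' @param tolerance_sampling expand torsion angles by tolerances.
#' @return List `conformers`, `ok`, `detail`.
#' @export
systematic_sample <- function(mol, param, frag_params, frag, libs,
                              lib = fragment_library(), window = 15,
                              tolerance_sampling = FALSE) {
  nfrag <- length(frag$fragments)
  capped_list <- attr(frag_params, "capped")
  conf_sets <- vector("list", nfrag)
  for (k in seq_len(nfrag)) {
    fclass <- classify_fragment(mol, frag$fragments[[k]])
    cs <- fragment_conformers(capped_list[[k]], fclass, frag_params[[k]], lib)
    if (is.null(cs)) {
      return(list(conformers = list(), ok = FALSE,
                  detail = sprintf("fragment %d conformer generation failed", k)))
    }
    conf_sets[[k]] <- cs
  }
  attr(conf_sets, "capped") <- capped_list
  fccs <- enumerate_fccs(conf_sets, window = window)
  prep <- prepare_torsion_drive(mol, param, frag, libs,
                                tolerance_sampling = tolerance_sampling)
  res <- drive_fccs(mol, param, prep, frag, conf_sets, fccs, window = window)
  list(conformers = res$conformers, ok = res$ok,
       detail = sprintf("%d fragments, %d FCCs, %d processed",
                        nfrag, nrow(fccs), res$fccs_processed))
}

#' Build capped fragments and parametrize them in one helper call
#'
#' @param mol `mol_graph`.
#' @param frag fragmentation result.
#' @param variant,no_estat force-field options (as for [parametrize()]).
#' @return List of `mmff_param` (one per fragment) with attribute
#'   `capped` carrying the capped fragment graphs.
#' @export
prepare_systematic <- function(mol, frag, variant = "MMFF94s",
                               no_estat = TRUE) {
  capped_list <- lapply(frag$fragments, function(fa) {
    capped_fragment(mol, fa, frag$link_bonds)
  })
  fp <- parametrize(capped_list, variant = variant, no_estat = no_estat)
  attr(fp, "capped") <- capped_list
  fp
}
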