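# Readers and writers: SMILES and SDF/MOL input via the RDKit bridge,
# V2000 multi-conformer SDF output, and deterministic fixture generation.

#' Parse molecules from SMILES strings
#'
#' @param smiles character vector of (isomeric) SMILES, '.'-separated
#'   components allowed.
#' @param names optional molecule names.
#' @return List of `mol_graph` objects; unparsable entries yield `NULL`
#'   with a warning.
#' @export
parse_smiles <- function(smiles, names = NULL) {
  recs <- lapply(seq_along(smiles), function(k) {
    r <- list(smiles = smiles[k])
    if (!is.null(names)) r$name <- names[k]
    r
  })
  res <- bridge_call(list(cmd = "parse", records = recs))
  lapply(seq_along(res), function(k) {
    g <- json_to_mol(res[[k]])
    if (is.null(g)) warning("skipping unparsable record ", k, ": ",
                            res[[k]]$error %||% "?", call. = FALSE)
    g
  })
}

#' Parse molecules from MOL/SDF record text
#' @param molblocks character vector, one V2000 block per element.
#' @return List of `mol_graph` (or `NULL` for bad records).
#' @export
parse_molblocks <- function(molblocks) {
  recs <- lapply(molblocks, function(mb) list(molblock = mb))
  res <- bridge_call(list(cmd = "parse", records = recs))
  lapply(res, json_to_mol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

json_to_mol <- function(x) {
  if (!isTRUE(x$ok)) return(NULL)
  atoms <- data.frame(
    element = vapply(x$atoms, function(a) a$el, ""),
    charge = vapply(x$atoms, function(a) as.integer(a$chg), 1L),
    nH = vapply(x$atoms, function(a) as.integer(a$nH), 1L),
    aromatic = vapply(x$atoms, function(a) isTRUE(a$arom), TRUE),
    cip = vapply(x$atoms, function(a) a$cip %||% NA_character_, ""))
  if (length(x$bonds)) {
    bonds <- data.frame(
      i = vapply(x$bonds, function(b) as.integer(b$i), 1L) + 1L,
      j = vapply(x$bonds, function(b) as.integer(b$j), 1L) + 1L,
      order = vapply(x$bonds, function(b) as.integer(b$order), 1L),
      aromatic = vapply(x$bonds, function(b) isTRUE(b$arom), TRUE))
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        aromatic = logical())
  }
  sa <- NULL
  if (length(x$stereo_atoms)) {
    sa <- data.frame(
      center = vapply(x$stereo_atoms, function(s) as.integer(s$center), 1L) + 1L,
      n1 = vapply(x$stereo_atoms, function(s) as.integer(s$nbrs[[1]]), 1L) + 1L,
      n2 = vapply(x$stereo_atoms, function(s) as.integer(s$nbrs[[2]]), 1L) + 1L,
      n3 = vapply(x$stereo_atoms, function(s) as.integer(s$nbrs[[3]]), 1L) + 1L,
      n4 = vapply(x$stereo_atoms, function(s) as.integer(s$nbrs[[4]]), 1L) + 1L,
      parity = vapply(x$stereo_atoms, function(s) as.integer(s$parity), 1L),
      cip = vapply(x$stereo_atoms, function(s) s$cip %||% NA_character_, ""))
  }
  sb <- NULL
  if (length(x$stereo_bonds)) {
    sb <- data.frame(
      a = vapply(x$stereo_bonds, function(s) as.integer(s$a), 1L) + 1L,
      b = vapply(x$stereo_bonds, function(s) as.integer(s$b), 1L) + 1L,
      ref_a = vapply(x$stereo_bonds, function(s) as.integer(s$ref_a), 1L) + 1L,
      ref_b = vapply(x$stereo_bonds, function(s) as.integer(s$ref_b), 1L) + 1L,
      config = vapply(x$stereo_bonds, function(s) s$config, ""),
      specified = TRUE)
  }
  coords <- NULL
  if (!is.null(x$coords)) {
    coords <- do.call(rbind, lapply(x$coords, function(p) unlist(p)))
    # hydrogens appended later have no input coordinates; keep heavy rows
  }
  mol_graph(atoms, bonds, name = x$name %||% "", coords = coords,
            stereo_atoms = sa, stereo_bonds = sb)
}

#' Serialise a molecule graph to a V2000 MOL block
#'
#' @param mol a `mol_graph`.
#' @param coords N x 3 coordinate matrix (Angstrom); zeros if omitted.
#' @param name title-line override.
#' @return A single string (LF line endings, trailing newline).
#' @export
write_molblock <- function(mol, coords = NULL, name = NULL) {
  n <- n_atoms(mol)
  m <- nrow(mol$bonds)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  lines <- c(name %||% mol$name, "  confsmith", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[a, 1], coords[a, 2], coords[a, 3],
                              mol$atoms$element[a]))
  }
  for (r in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i[r],
                              mol$bonds$j[r], mol$bonds$order[r]))
  }
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg)) {
    for (start in seq(1, length(chg), by = 8)) {
      idx <- chg[start:min(start + 7, length(chg))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(idx)),
                               paste0(sprintf("%4d%4d", idx,
                                              mol$atoms$charge[idx]),
                                      collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read compounds from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line (whitespace-separated optional
#' name); SDF records are split at `$$$$`. Unparsable records are skipped
#' with a warning and do not stop the iteration.
#'
#' @param path input file.
#' @param format "smiles", "sdf", or "auto" (by extension).
#' @return List of `mol_graph` objects.
#' @export
read_compounds <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE)) "sdf"
              else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(list())
    parts <- strsplit(trimws(lines), "\\s+")
    smi <- vapply(parts, `[`, "", 1)
    nms <- vapply(parts, function(p) if (length(p) > 1) paste(p[-1], collapse = " ") else "", "")
    mols <- parse_smiles(smi, nms)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
    recs <- recs[nzchar(trimws(recs))]
    if (!length(recs)) return(list())
    mols <- parse_molblocks(recs)
    bad <- vapply(mols, is.null, TRUE)
    if (any(bad)) warning(sum(bad), " unparsable SDF record(s) skipped",
                          call. = FALSE)
  }
  Filter(Negate(is.null), mols)
}

#' Write a conformer ensemble as a multi-record SDF
#'
#' One V2000 record per conformer with `<Energy>` (kcal/mol, four
#' decimals), `<Name>` and `<ConformerIndex>` data tags.
#'
#' @param ensemble a `conformer_ensemble` (see [compile_output_ensemble()]).
#' @param path output file path or connection.
#' @param append append to an existing file.
#' @return Invisibly, the number of records written.
#' @export
write_ensemble <- function(ensemble, path, append = FALSE) {
  mol <- ensemble$mol
  k <- 0L
  out <- character(0)
  for (conf in ensemble$conformers) {
    k <- k + 1L
    block <- write_molblock(mol, conf$coords)
    out <- c(out, sub("\n$", "", block),
             "> <Energy>", sprintf("%.4f", conf$energy), "",
             "> <Name>", mol$name, "",
             "> <ConformerIndex>", as.character(k), "",
             "$$$$")
  }
  if (length(out)) {
    con <- file(path, if (append) "ab" else "wb")
    writeLines(out, con, sep = "\n")
    close(con)
  } else if (!append) {
    file.create(path)
  }
  invisible(k)
}

#' Read a multi-conformer SDF back into coordinate sets
#'
#' Light-weight reader for files produced by [write_ensemble()]: returns
#' coordinates and tags without re-perceiving chemistry.
#'
#' @param path SDF file.
#' @return List with one entry per record: `coords`, `energy`, `name`,
#'   `index`.
#' @export
read_ensemble_sdf <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  lapply(recs, function(rec) {
    lines <- strsplit(rec, "\n")[[1]]
    counts <- lines[4]
    na <- as.integer(substr(counts, 1, 3))
    coords <- matrix(NA_real_, na, 3)
    els <- character(na)
    for (a in seq_len(na)) {
      ln <- lines[4 + a]
      coords[a, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                  substr(ln, 21, 30)))
      els[a] <- trimws(substr(ln, 31, 34))
    }
    tag <- function(nm) {
      hit <- grep(paste0("^> <", nm, ">$"), lines)
      if (length(hit)) lines[hit[1] + 1] else NA_character_
    }
    list(coords = coords, elements = els,
         energy = as.numeric(tag("Energy")),
         name = tag("Name"),
         index = as.integer(tag("ConformerIndex")))
  })
}

# ---------------------------------------------------------------------------
# Deterministic synthetic fixtures

FIXTURE_CORES <- c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C1CCCCC1",
                   "C1CCOCC1", "c1ccoc1", "c1ccsc1", "C1CCNCC1", "c1cnoc1")
FIXTURE_LINKERS <- c("CC", "CCC", "CC(C)", "COC", "CNC", "CC(=O)N", "CC(=O)O",
                     "C(=O)N", "CCO", "CSC")
FIXTURE_CAPS <- c("C", "CC", "O", "N", "F", "Cl", "C(C)C", "OC", "C#N",
                  "C(F)(F)F", "S(=O)(=O)N")
# prefix-safe cap spellings (used when the cap starts the SMILES string)
FIXTURE_CAPS_PRE <- c("C", "CC", "O", "N", "FC(F)(F)", "N#C", "CC(C)", "CO")
FIXTURE_STEREO <- c("C[C@H](N)C(=O)O", "C[C@@H](O)CC", "C/C=C/C(N)=O",
                    "C[C@H](F)c1ccccc1", "O[C@@H]1CCCC[C@H]1N",
                    "C/C=C/CO", "C[C@@H](Cl)/C=C/C", "N[C@@H](CO)C(=O)O",
                    "C[C@H]1CC[C@@H](O)CC1", "F[C@H](Cl)C(=O)NC")

#' Generate deterministic synthetic molecule fixtures
#'
#' Writes a SMILES file with reproducible synthetic molecules of four
#' flavours: `smallmol` (drug-like assemblies of ring cores, linkers and
#' substituent caps, at most eight rotatable bonds), `macrocycle`
#' (saturated 12- to 24-membered rings with occasional ether oxygens and
#' methyl substituents), `salt` (multi-component records), `stereo`
#' (molecules with at least one defined tetrahedral centre or double-bond
#' geometry). The chemistry is restricted to MMFF94-covered elements.
#'
#' @param kind fixture flavour.
#' @param n number of molecules.
#' @param seed RNG seed (fixtures are byte-identical for equal seeds).
#' @param path output file; a tempfile by default.
#' @return The path, invisibly; attribute `smiles` carries the strings.
#' @export
make_fixtures <- function(kind = c("smallmol", "macrocycle", "salt", "stereo"),
                          n, seed = 1L, path = tempfile(fileext = ".smi")) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  set.seed(seed)
  smi <- character(n)
  for (k in seq_len(n)) {
    smi[k] <- switch(kind,
      smallmol = {
        core <- sample(FIXTURE_CORES, 1)
        linker <- sample(FIXTURE_LINKERS, 1)
        if (runif(1) < 0.5) {
          paste0(sample(FIXTURE_CAPS_PRE, 1), linker, core)
        } else {
          paste0(core, linker, sample(FIXTURE_CAPS, 1))
        }
      },
      macrocycle = {
        size <- sample(12:24, 1)
        atoms <- rep("C", size)
        n_o <- sample(0:2, 1)
        if (n_o > 0) {
          pos <- sample(2:(size - 1), n_o)
          atoms[pos] <- "O"
        }
        body <- paste(atoms[-1], collapse = "")
        ring <- paste0(atoms[1], "1", body, "1")
        if (runif(1) < 0.4) sub("1(C+)", "1C(C)\\1", ring) else ring
      },
      salt = {
        anion <- sample(c("CC(=O)[O-]", "[Cl-]", "CS(=O)(=O)[O-]"), 1)
        cation <- sample(c("[Na+]", "C[NH3+]", "CC[NH3+]"), 1)
        paste0(anion, ".", cation)
      },
      stereo = {
        base <- sample(FIXTURE_STEREO, 1)
        base
      })
  }
  writeLines(paste(smi, paste0(kind, "_", seq_len(n))), path)
  structure(invisible(path), smiles = smi)
}
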