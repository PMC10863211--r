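# Readers and writers for the standard formats the pipeline touches:
# SDF V2000, SMILES, FASTA, PDB.  All text readers accept gzip through
# R's transparent connection handling.

#' Read an SDF (V2000) file into a molecule library
#'
#' Each record becomes one [molecule()]; a 3D coordinate block becomes a
#' conformer, SD tags land in `properties`. Malformed records are
#' skipped with a warning naming the record index; parsing continues.
#'
#' @param path Path to an SDF file (optionally gzip-compressed).
#' @return List of `ps_mol` objects (possibly empty), with an attribute
#'   `errors`: a tibble of skipped record indices and messages.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    return(structure(list(), errors = tibble::tibble(record = integer(),
                                                     message = character())))
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends) || utils::tail(ends, 1) < length(lines)) {
    ends <- c(ends, length(lines))
  }
  starts <- c(1L, head(ends, -1) + 1L)
  mols <- list()
  errs <- list()
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    m <- tryCatch(parse_sdf_record(rec, fallback_id = sprintf("mol%03d", k)),
                  error = function(e) e)
    if (inherits(m, "error")) {
      errs[[length(errs) + 1]] <- tibble::tibble(record = k,
                                                 message = conditionMessage(m))
      warn(sprintf("SDF record %d skipped: %s", k, conditionMessage(m)))
    } else {
      mols[[length(mols) + 1]] <- m
    }
  }
  structure(mols,
            errors = if (length(errs)) dplyr::bind_rows(errs)
                     else tibble::tibble(record = integer(), message = character()))
}

# One V2000 record (character vector, no terminator) -> ps_mol.
# ChemmineR does the block parsing; charges are completed from the
# M  CHG property lines, which carry the authoritative formal charges.
parse_sdf_record <- function(rec, fallback_id = "mol") {
  if (length(rec) < 4) abort("record too short")
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) abort("unreadable counts line")
  if (length(rec) < 4 + na + nb) abort("truncated atom/bond block")
  parsed <- tryCatch({
    sdfset <- suppressWarnings(
      methods::as(methods::new(methods::getClass("SDFstr", where = asNamespace("ChemmineR")), a = list(c(rec, "$$$$"))), "SDFset"))
    sdf <- sdfset[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (nrow(ab) != na) stop("atom block length mismatch")
    el <- sub("_.*$", "", rownames(ab))
    if (!all(grepl("^[A-Za-z]", el))) stop("garbled atom block")
    list(ab = ab, bb = bb, props = as.list(ChemmineR::datablock(sdf)))
  }, error = function(e) NULL)
  if (is.null(parsed)) {
    # ChemmineR rejects degenerate records (e.g. single-atom, no-bond
    # molecules); parse the fixed-width V2000 blocks directly
    atom_lines <- rec[5:(4 + na)]
    ab <- do.call(rbind, lapply(atom_lines, function(ln) {
      c(as.numeric(substr(ln, 1, 10)), as.numeric(substr(ln, 11, 20)),
        as.numeric(substr(ln, 21, 30)), 0,
        as.numeric(substr(ln, 37, 39)))
    }))
    if (any(!is.finite(ab[, 1:3]))) abort("unreadable atom block")
    colnames(ab) <- c("C1", "C2", "C3", "C5", "C6")
    rownames(ab) <- paste(vapply(atom_lines, function(ln)
      trimws(substr(ln, 32, 34)), character(1)), seq_len(na), sep = "_")
    bb <- matrix(numeric(0), 0, 3)
    if (nb > 0) {
      bond_lines <- rec[(5 + na):(4 + na + nb)]
      bb <- do.call(rbind, lapply(bond_lines, function(ln) {
        c(as.numeric(substr(ln, 1, 3)), as.numeric(substr(ln, 4, 6)),
          as.numeric(substr(ln, 7, 9)))
      }))
    }
    tag_idx <- grep("^> *<", rec)
    props <- list()
    for (ti in tag_idx) {
      nm <- sub("^> *<([^>]+)>.*$", "\\1", rec[ti])
      if (ti + 1 <= length(rec)) props[[nm]] <- rec[ti + 1]
    }
    parsed <- list(ab = ab, bb = bb, props = props)
  }
  ab <- parsed$ab
  bb <- parsed$bb
  element <- sub("_.*$", "", rownames(ab))
  bad <- !(element %in% c(names(STD_VALENCE), "Na", "K", "Li", "Ca", "Mg",
                          "Zn", "Fe", "Cu", "Mn", "Al", "As", "Sn"))
  if (any(bad)) abort(sprintf("unknown element symbol '%s'", element[bad][1]))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charge <- integer(na)
  # old-style charge codes live in the block column labelled C6
  if ("C6" %in% colnames(ab)) {
    code <- ab[, "C6"]
    charge <- ifelse(code %in% 1:7 & code != 4, 4L - as.integer(code), 0L)
  }
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(na)  # M CHG supersedes all old-style codes
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      npair <- f[1]
      for (p in seq_len(npair)) {
        charge[f[2 * p]] <- f[2 * p + 1]
      }
    }
  }
  bonds <- tibble::tibble(
    i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
    order = as.numeric(bb[, 3]))
  props <- parsed$props
  id <- trimws(rec[1])
  if (!nzchar(id)) id <- fallback_id
  if (!is.null(props[["id"]])) id <- props[["id"]]
  dim3 <- any(abs(coords[, 3]) > 1e-8) || grepl("3D", rec[2], fixed = TRUE)
  molecule(id = id,
           atoms = tibble::tibble(element = element, charge = charge),
           bonds = bonds,
           conformers = if (dim3) list(conf1 = coords) else list(),
           properties = props[setdiff(names(props), "id")])
}

# Render one ps_mol as V2000 record lines (without the $$$$ terminator).
mol_to_sdf_lines <- function(mol, conformer = 1L) {
  n <- nrow(mol$atoms)
  has3d <- length(mol$conformers) >= 1
  coords <- if (has3d) mol$conformers[[conformer]] else matrix(0, n, 3)
  dim_flag <- if (has3d) "3D" else "2D"
  header <- c(mol$id, sprintf("  pharmscreen          %s", dim_flag), "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    n, nrow(mol$bonds))
  atoms <- vapply(seq_len(n), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3], mol$atoms$element[i])
  }, character(1))
  bonds <- character(0)
  if (nrow(mol$bonds)) {
    bonds <- vapply(seq_len(nrow(mol$bonds)), function(k) {
      sprintf("%3d%3d%3d  0", mol$bonds$i[k], mol$bonds$j[k],
              as.integer(round(mol$bonds$order[k])))
    }, character(1))
  }
  chg <- which(mol$atoms$charge != 0)
  chg_lines <- character(0)
  if (length(chg)) {
    grp <- split(chg, ceiling(seq_along(chg) / 8))
    chg_lines <- vapply(grp, function(g) {
      paste0("M  CHG", sprintf("%3d", length(g)),
             paste0(sprintf("%4d%4d", g, mol$atoms$charge[g]), collapse = ""))
    }, character(1))
  }
  tags <- character(0)
  if (length(mol$properties)) {
    tags <- unlist(lapply(names(mol$properties), function(nm) {
      c(sprintf(">  <%s>", nm), as.character(mol$properties[[nm]]), "")
    }))
  }
  c(header, counts, atoms, bonds, chg_lines, "M  END", tags)
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols A `ps_mol` or list of them.
#' @param path Output path.
#' @param conformer Which conformer to write (index or name); molecules
#'   without 3D coordinates are written as 2D records with zero
#'   coordinates.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, conformer = 1L) {
  if (is_molecule(mols)) mols <- list(mols)
  out <- unlist(lapply(mols, function(m) c(mol_to_sdf_lines(m, conformer), "$$$$")))
  writeLines(out, path)
  invisible(path)
}

# Library -> ChemmineR SDFset (via in-memory V2000 text).
to_sdfset <- function(mols) {
  if (is_molecule(mols)) mols <- list(mols)
  recs <- lapply(mols, function(m) c(mol_to_sdf_lines(m), "$$$$"))
  set <- methods::as(methods::new(methods::getClass("SDFstr", where = asNamespace("ChemmineR")), a = recs), "SDFset")
  ChemmineR::cid(set) <- vapply(mols, function(m) m$id, character(1))
  set
}

# Library -> concatenated V2000 text (OpenBabel-facing operations work
# on text so degenerate records like single-atom molecules survive).
ob_text <- function(mols) {
  if (is_molecule(mols)) mols <- list(mols)
  paste0(paste(unlist(lapply(mols, function(m) c(mol_to_sdf_lines(m), "$$$$"))),
               collapse = "\n"), "\n")
}

# Per-molecule OpenBabel descriptor table (MW, logP, TPSA, HBD, ...).
ob_props <- function(mols) {
  rows <- ChemmineOB::forEachMol("SDF", ob_text(mols), function(m)
    ChemmineOB::prop_OB(m))
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# Per-molecule unique SMARTS match counts.
ob_smarts_count <- function(mols, pattern) {
  res <- ChemmineOB::forEachMol("SDF", ob_text(mols), function(m)
    ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE))
  as.integer(unlist(res))
}

#' Parse SMILES strings into molecules
#'
#' @param smiles Character vector of SMILES.
#' @param ids Identifiers (defaults to names of `smiles` or `mol<k>`).
#' @param keep_3d Generate 3D coordinates for each molecule (slower).
#' @return List of `ps_mol`.
#' @export
parse_smiles <- function(smiles, ids = NULL, keep_3d = FALSE) {
  if (is.null(ids)) {
    ids <- names(smiles) %||% sprintf("mol%03d", seq_along(smiles))
  }
  stopifnot(length(ids) == length(smiles))
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    src <- paste0(unname(smiles[k]), " ", ids[k], "\n")
    txt <- tryCatch(
      if (keep_3d) {
        ChemmineOB::convertFormat("SMI", "SDF", source = src,
                                  options = data.frame(names = "gen3D",
                                                       args = "fastest"))
      } else {
        ChemmineOB::convertFormat("SMI", "SDF", source = src)
      },
      error = function(e) "")
    rec <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (length(rec) < 4) {
      abort(sprintf("SMILES %d ('%s') could not be parsed", k, smiles[k]))
    }
    m <- tryCatch(parse_sdf_record(rec, fallback_id = ids[k]),
                  error = function(e) {
                    abort(sprintf("SMILES %d ('%s') could not be parsed",
                                  k, smiles[k]))
                  })
    m$id <- ids[k]
    m$smiles <- smiles[k]
    if (!keep_3d) m$conformers <- list()
    out[[k]] <- m
  }
  out
}

#' Read a SMILES file
#'
#' One molecule per line, `SMILES[ whitespace ID]`. Lines that fail to
#' parse raise an error naming the line.
#'
#' @param path Path to the file (optionally gzipped).
#' @return List of `ps_mol`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    id <- if (length(f) >= 2) f[2] else sprintf("mol%03d", k)
    out[[k]] <- tryCatch(parse_smiles(f[1], id)[[1]], error = function(e) {
      abort(sprintf("line %d of %s: invalid SMILES '%s'", k, path, f[1]))
    })
  }
  out
}

#' Canonical structure key
#'
#' Canonical SMILES of the (standardized) structure, used as the
#' duplicate key throughout the filtration cascade.
#'
#' @param mols A `ps_mol` or list of them.
#' @return Character vector of canonical SMILES.
#' @export
canonical_key <- function(mols) {
  if (is_molecule(mols)) mols <- list(mols)
  if (!length(mols)) return(character(0))
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = ob_text(mols))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(mols)) {
    abort("canonical SMILES conversion dropped records")
  }
  vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
}

#' Read sequence records from FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return Tibble with columns `id` and `residues` (one-letter amino
#'   acid codes; alphabet restricted to the 20 standard letters plus X).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  res <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(res))
  if (any(bad)) {
    abort(sprintf("sequence '%s' contains letters outside the 20 standard amino acids + X",
                  ids[bad][1]))
  }
  tibble::tibble(id = ids, residues = toupper(unname(res)))
}

#' Read a protein structure from PDB
#'
#' @param path PDB file.
#' @param chain Optional chain identifier(s) to retain (e.g. `"A"`,
#'   mirroring the common practice of keeping chain A only).
#' @param keep_het Keep HETATM records (ligands, cofactors).
#' @return A `ps_protein`: list with an `atoms` tibble (`chain`,
#'   `resno`, `ins`, `resid`, `elety`, `element`, `x`, `y`, `z`, `het`).
#' @export
read_pdb <- function(path, chain = NULL, keep_het = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- tibble::tibble(
    chain = a$chain, resno = a$resno,
    ins = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid, elety = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM")
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (!keep_het) atoms <- atoms[!atoms$het, , drop = FALSE]
  if (!all(is.finite(atoms$x + atoms$y + atoms$z))) {
    abort(sprintf("non-finite coordinates in %s", path))
  }
  new_protein(atoms, source = path)
}

#' Construct a protein structure object
#'
#' @param atoms Tibble with at least `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z`; optional `ins` and `het`.
#' @param source Free-form provenance string.
#' @return A `ps_protein`.
#' @export
new_protein <- function(atoms, source = "constructed") {
  atoms <- tibble::as_tibble(atoms)
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  structure(list(atoms = atoms, source = source), class = "ps_protein")
}

#' @export
print.ps_protein <- function(x, ...) {
  prot <- x$atoms[!x$atoms$het, ]
  cat(sprintf("<ps_protein> %d atoms, %d residues, chains: %s (%d HETATM)\n",
              nrow(x$atoms),
              nrow(unique(prot[, c("chain", "resno", "ins")])),
              paste(unique(x$atoms$chain), collapse = ","),
              sum(x$atoms$het)))
  invisible(x)
}

#' Extract a HETATM group as a molecule-like object
#'
#' @param protein A `ps_protein`.
#' @param resid Residue name of the ligand; default: the largest
#'   non-water HETATM group.
#' @return A `ps_mol` (no bond information) with one conformer.
#' @export
pdb_ligand <- function(protein, resid = NULL) {
  het <- protein$atoms[protein$atoms$het &
                         !protein$atoms$resid %in% c("HOH", "WAT"), ]
  if (!nrow(het)) abort("no HETATM ligand in structure")
  if (is.null(resid)) {
    resid <- names(sort(table(het$resid), decreasing = TRUE))[1]
  }
  lig <- het[het$resid == resid, ]
  molecule(id = resid,
           atoms = tibble::tibble(element = lig$element, charge = 0L),
           conformers = list(conf1 = cbind(lig$x, lig$y, lig$z)))
}
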