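# The in-memory molecule container.  A `ps_mol` is a light S3 list:
#   id         molecule identifier (unique within a library)
#   atoms      tibble: element, charge, aromatic
#   bonds      tibble: i, j, order (indices into atoms)
#   conformers named list of n_atom x 3 coordinate matrices (Angstrom)
#   properties named list of SD-tag style key/value pairs
#   smiles     canonical line notation when known (see canonical_key())
# Chemistry perception that needs a real toolkit (aromaticity, canonical
# SMILES, descriptors, SMARTS alerts) is delegated to ChemmineR/ChemmineOB;
# everything graph-topological is computed here.

STD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                 Br = 1, I = 1, B = 3, Si = 4, Se = 2, H = 1)

#' Construct a molecule
#'
#' @param id Molecule identifier.
#' @param atoms Tibble or data frame with columns `element` (chemical
#'   symbol) and optionally `charge` (formal charge, default 0) and
#'   `aromatic` (logical).
#' @param bonds Tibble with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3; aromatic bonds may carry 1.5).
#' @param conformers List of n_atom x 3 coordinate matrices (Angstrom).
#' @param properties Named list of free-form properties (SD tags).
#' @param smiles Optional canonical line notation.
#' @return An object of class `ps_mol`.
#' @export
molecule <- function(id, atoms, bonds = NULL, conformers = list(),
                     properties = list(), smiles = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  if (!"aromatic" %in% names(atoms)) atoms$aromatic <- FALSE
  if (is.null(bonds)) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = numeric())
  }
  bonds <- tibble::as_tibble(bonds)
  n <- nrow(atoms)
  if (nrow(bonds) && (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))) {
    abort(sprintf("molecule '%s': bond atom indices out of range", id))
  }
  conformers <- lapply(conformers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) != n) {
      abort(sprintf("molecule '%s': conformer has %d coordinate rows for %d atoms",
                    id, nrow(m), n))
    }
    if (!all(is.finite(m))) abort(sprintf("molecule '%s': non-finite coordinates", id))
    dimnames(m) <- NULL
    m
  })
  if (length(conformers) && is.null(names(conformers))) {
    names(conformers) <- paste0("conf", seq_along(conformers))
  }
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         conformers = conformers, properties = properties,
         smiles = smiles),
    class = "ps_mol")
}

#' @export
print.ps_mol <- function(x, ...) {
  cat(sprintf("<ps_mol> %s: %d atoms (%d heavy), %d bonds, %d conformer(s)\n",
              x$id, nrow(x$atoms), sum(x$atoms$element != "H"),
              nrow(x$bonds), length(x$conformers)))
  if (!is.na(x$smiles)) cat("  smiles:", x$smiles, "\n")
  invisible(x)
}

is_molecule <- function(x) inherits(x, "ps_mol")

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

# Adjacency list over all atoms.
adjacency <- function(mol) {
  adj <- vector("list", nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Connected components of the molecular graph; integer component id per atom.
fragment_ids <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b in adj[[a]]) {
        if (comp[b] == 0L) { comp[b] <- cur; queue <- c(queue, b) }
      }
    }
  }
  comp
}

# Sum of bond orders incident to each atom (aromatic bonds count 1.5
# when flagged, otherwise their kekulized order).
degree_order <- function(mol) {
  n <- nrow(mol$atoms)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + o
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + o
    }
  }
  s
}

#' Implicit hydrogen counts
#'
#' Number of implicit hydrogens per atom under a standard valence model
#' (C 4, N 3, O 2, ... adjusted by formal charge). Explicit hydrogens in
#' the graph reduce the implicit count like any other neighbour.
#'
#' @param mol A [molecule()].
#' @return Integer vector, one entry per atom.
#' @export
implicit_hydrogens <- function(mol) {
  el <- mol$atoms$element
  ch <- mol$atoms$charge
  std <- unname(STD_VALENCE[el])
  std[is.na(std)] <- 0
  eff <- ifelse(el == "C", std - abs(ch), std + ch)
  used <- degree_order(mol)
  # Kekulized aromatic rings already carry alternating single/double
  # bonds, so no aromatic correction is needed here.
  pmax(0L, as.integer(round(eff - used)))
}

# Total attached hydrogens (explicit + implicit) per atom.
hydrogen_count <- function(mol) {
  nH_exp <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    hs <- mol$atoms$element == "H"
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (hs[j]) nH_exp[i] <- nH_exp[i] + 1L
      if (hs[i]) nH_exp[j] <- nH_exp[j] + 1L
    }
  }
  nH_exp + implicit_hydrogens(mol)
}

# Rings + aromaticity are delegated to ChemmineR's perception on an SDF
# rendering of the molecule; results are cached on the object.
perceive_rings <- function(mol) {
  if (!is.null(mol$rings)) return(mol$rings)
  if (!nrow(mol$bonds)) return(list(rings = list(), aromatic = logical()))
  sdf <- to_sdfset(list(mol))[[1]]
  out <- tryCatch(
    ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE),
    error = function(e) list(RINGS = list(), AROMATIC = logical()))
  ring_idx <- lapply(out$RINGS, function(r) {
    as.integer(sub("^[A-Za-z]+_", "", r))
  })
  list(rings = ring_idx, aromatic = as.logical(out$AROMATIC))
}

# Logical per-atom aromatic flag from ring perception.
aromatic_atoms <- function(mol) {
  flag <- logical(nrow(mol$atoms))
  ri <- perceive_rings(mol)
  if (length(ri$rings)) {
    for (k in seq_along(ri$rings)) {
      if (isTRUE(ri$aromatic[k])) flag[ri$rings[[k]]] <- TRUE
    }
  }
  flag | mol$atoms$aromatic
}
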