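# Perception of pharmacophoric points on a 3D conformer: hydrogen bond
# acceptors (ACC), donors (DON), projected donors (DON_PROJ), aromatic
# ring centroids (ARO) and hydrophobic group centroids (HYD).  The
# chemistry is driven by an editable rule dictionary shipped with the
# package (inst/extdata/feature_rules.tsv), so feature definitions can
# be audited and swapped without touching code.

FEATURE_KINDS <- c("ACC", "DON", "DON_PROJ", "ARO", "HYD")

#' Read a feature-perception rule dictionary
#'
#' The dictionary is a tab-separated file with columns `kind`, `rule`
#' and `params` (semicolon-separated `key=value` pairs). The shipped
#' default encodes conventional pharmacophore feature definitions:
#' lone-pair N/O acceptors with the amide nitrogen excluded, N-H/O-H
#' donors, aromatic ring centroids, and centroids of contiguous apolar
#' carbon groups of at least three atoms (ring or chain; halogens on
#' such carbons included).
#'
#' @param path Path to a rules file; default: the package dictionary.
#' @return Tibble with columns `kind`, `rule`, `params` (named list).
#' @export
read_feature_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_rules.tsv",
                                package = "pharmscreen")
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("kind", "rule") %in% names(raw))) {
    abort("feature rules file needs columns kind, rule, params")
  }
  bad <- !raw$kind %in% FEATURE_KINDS
  if (any(bad)) abort(sprintf("unknown feature kind '%s'", raw$kind[bad][1]))
  raw$params <- lapply(ifelse(is.na(raw$params), "", raw$params), function(s) {
    if (!nzchar(s)) return(list())
    kv <- strsplit(strsplit(s, ";")[[1]], "=")
    setNames(lapply(kv, function(p) utils::type.convert(p[2], as.is = TRUE)),
             vapply(kv, `[`, character(1), 1))
  })
  tibble::as_tibble(raw[c("kind", "rule", "params")])
}

new_feature_set <- function(points, molecule_id, conformer = "conf1") {
  points <- tibble::as_tibble(points)
  structure(points, class = c("ph4_features", class(points)),
            molecule_id = molecule_id, conformer = conformer)
}

#' Construct a feature set directly
#'
#' The matcher consumes feature sets, so fixtures (synthetic feature
#' clouds) can bypass chemistry entirely.
#'
#' @param kind Character vector of feature kinds (`ACC`, `DON`,
#'   `DON_PROJ`, `ARO`, `HYD`).
#' @param coords n x 3 matrix of positions (Angstrom).
#' @param molecule_id,conformer Identifiers carried along.
#' @param label Optional labels (default `<KIND><k>`).
#' @return A `ph4_features` tibble: `kind`, `x`, `y`, `z`, `label`,
#'   `source_atoms` (list), `parent`.
#' @export
feature_set <- function(kind, coords, molecule_id = "fixture",
                        conformer = "conf1", label = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == length(kind),
            all(kind %in% FEATURE_KINDS), all(is.finite(coords)))
  if (is.null(label)) {
    label <- paste0(kind, stats::ave(seq_along(kind), kind, FUN = seq_along))
  }
  pts <- tibble::tibble(kind = kind, x = coords[, 1], y = coords[, 2],
                        z = coords[, 3], label = label,
                        source_atoms = replicate(length(kind), integer(0),
                                                 simplify = FALSE),
                        parent = NA_character_)
  pts <- sort_features(pts)
  new_feature_set(pts, molecule_id, conformer)
}

# Deterministic ordering: kind (fixed order), then position.
sort_features <- function(pts) {
  ord <- order(match(pts$kind, FEATURE_KINDS),
               round(pts$x, 6), round(pts$y, 6), round(pts$z, 6))
  pts[ord, , drop = FALSE]
}

feature_coords <- function(fs) {
  as.matrix(fs[, c("x", "y", "z")])
}

#' Perceive pharmacophoric points on a conformer
#'
#' @param mol A [molecule()] with at least one conformer.
#' @param conformer Conformer index or name (default first).
#' @param rules Rule dictionary from [read_feature_rules()].
#' @return A `ph4_features` tibble (see [feature_set()]); positions of
#'   ACC/DON coincide with their heavy atom, ARO/HYD are centroids of
#'   their source atoms.
#' @export
perceive_features <- function(mol, conformer = 1L, rules = read_feature_rules()) {
  stopifnot(is_molecule(mol))
  if (!length(mol$conformers)) abort(sprintf("molecule '%s' has no conformer", mol$id))
  coords <- mol$conformers[[conformer]]
  if (nrow(coords) != nrow(mol$atoms)) abort("conformer/molecule atom-count mismatch")
  conf_label <- names(mol$conformers)[[if (is.character(conformer))
    which(names(mol$conformers) == conformer) else conformer]]

  el <- mol$atoms$element
  adj <- adjacency(mol)
  arom <- aromatic_atoms(mol)
  nH <- hydrogen_count(mol)
  charge <- mol$atoms$charge
  pts <- list()
  add <- function(kind, pos, source, parent = NA_character_) {
    pts[[length(pts) + 1]] <<- tibble::tibble(
      kind = kind, x = pos[1], y = pos[2], z = pos[3], label = NA_character_,
      source_atoms = list(as.integer(source)), parent = parent)
  }

  has_rule <- function(kind, rule) {
    any(rules$kind == kind & rules$rule == rule)
  }
  rule_param <- function(kind, rule, key, default) {
    row <- which(rules$kind == kind & rules$rule == rule)
    if (!length(row)) return(default)
    rules$params[[row[1]]][[key]] %||% default
  }

  amide_n <- vapply(seq_along(el), function(a) {
    el[a] == "N" && any(vapply(adj[[a]], function(nb)
      el[nb] == "C" && any(vapply(adj[[nb]], function(x)
        el[x] == "O" && bond_order(mol, nb, x) == 2, logical(1))),
      logical(1)))
  }, logical(1))

  if (has_rule("ACC", "lone_pair_NO")) {
    for (a in which(el %in% c("N", "O"))) {
      if (charge[a] > 0) next
      if (el[a] == "N") {
        if (amide_n[a]) next                  # amide N: no lone pair available
        if (arom[a] && nH[a] >= 1) next       # pyrrole-type N-H
        if (!arom[a] && degree_order(mol)[a] >= 4) next
      }
      add("ACC", coords[a, ], a)
    }
  }
  if (has_rule("DON", "polar_H")) {
    for (a in which(el %in% c("N", "O"))) {
      if (nH[a] >= 1 && charge[a] >= 0) add("DON", coords[a, ], a)
    }
  }
  if (has_rule("ARO", "ring_centroid")) {
    ri <- perceive_rings(mol)
    for (k in seq_along(ri$rings)) {
      if (!isTRUE(ri$aromatic[k])) next
      ring <- ri$rings[[k]]
      add("ARO", colMeans(coords[ring, , drop = FALSE]), ring)
    }
  }
  if (has_rule("HYD", "apolar_group")) {
    min_atoms <- rule_param("HYD", "apolar_group", "min_atoms", 3)
    with_halogens <- isTRUE(rule_param("HYD", "apolar_group", "halogens", TRUE))
    hetero <- c("N", "O", "S", "P")
    apolar <- el == "C" & !vapply(seq_along(el), function(a)
      any(el[adj[[a]]] %in% hetero), logical(1))
    groups <- apolar_components(adj, apolar)
    for (g in groups) {
      members <- g
      if (with_halogens) {
        hal <- unlist(lapply(g, function(a)
          adj[[a]][el[adj[[a]]] %in% c("F", "Cl", "Br", "I")]))
        members <- sort(unique(c(g, hal)))
      }
      if (length(g) >= min_atoms) {
        add("HYD", colMeans(coords[members, , drop = FALSE]), members)
      }
    }
  }

  pts <- if (length(pts)) dplyr::bind_rows(pts) else
    tibble::tibble(kind = character(), x = numeric(), y = numeric(),
                   z = numeric(), label = character(),
                   source_atoms = list(), parent = character())
  pts <- sort_features(pts)
  if (nrow(pts)) {
    pts$label <- paste0(pts$kind, stats::ave(seq_len(nrow(pts)), pts$kind,
                                             FUN = seq_along))
  }
  new_feature_set(pts, mol$id, conf_label)
}

bond_order <- function(mol, i, j) {
  hit <- (mol$bonds$i == i & mol$bonds$j == j) |
    (mol$bonds$i == j & mol$bonds$j == i)
  if (any(hit)) mol$bonds$order[hit][1] else 0
}

# Connected components restricted to flagged atoms.
apolar_components <- function(adj, flag) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in which(flag)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b in adj[[a]]) {
        if (flag[b] && comp[b] == 0L) { comp[b] <- cur; queue <- c(queue, b) }
      }
    }
  }
  if (!cur) return(list())
  lapply(seq_len(cur), function(k) sort(which(comp == k)))
}

#' Project a donor feature along its D-H direction
#'
#' Places a `DON_PROJ` point at `distance` Angstrom from the donor heavy
#' atom along the donor-to-hydrogen unit vector, marking where the
#' acceptor of the receptor is expected to sit.
#'
#' @param donor Length-3 position of the donor heavy atom.
#' @param h_position Length-3 position of its hydrogen.
#' @param distance Projection distance in Angstrom (default 2.8, a
#'   typical heavy-atom hydrogen-bond separation).
#' @param parent Label of the parent DON point.
#' @return One-row `ph4_features`-shaped tibble with kind `DON_PROJ`.
#' @export
project_donor <- function(donor, h_position, distance = 2.8, parent = "DON1") {
  v <- h_position - donor
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) abort("zero-length donor->hydrogen vector")
  pos <- donor + v / nrm * distance
  tibble::tibble(kind = "DON_PROJ", x = pos[1], y = pos[2], z = pos[3],
                 label = paste0(parent, "_proj"),
                 source_atoms = list(integer(0)), parent = parent)
}
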