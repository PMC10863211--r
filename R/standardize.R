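# Structure standardization ahead of screening: salt stripping and a
# conservative protonation model for aqueous near-neutral pH.  Strong
# acids are deprotonated, strong bases protonated; groups whose pKa sits
# too close to 7 to call are left exactly as input.

#' Standardize a molecule
#'
#' Keeps the largest organic fragment (salt strip; a fragment without
#' carbon is dropped whenever a carbon-bearing fragment exists), applies
#' the near-neutral-pH protonation rules, and recomputes the canonical
#' structure key. The operation is idempotent.
#'
#' Protonation rules, applied to the parent fragment:
#' * carboxylic and sulfonic acid O-H: deprotonated (charge -1);
#' * aliphatic amines (N with only single bonds, no adjacent carbonyl,
#'   non-aromatic) and amidine/guanidine =N-: protonated (charge +1);
#' * everything else (phenols, amides, anilines, heteroaromatic N-H,
#'   alcohols): left in the input protonation state, reflecting the rule
#'   that ambiguous-pKa groups keep the unionized input form.
#'
#' @param mol A [molecule()].
#' @return The standardized `ps_mol` (with `smiles` set to the canonical
#'   key of the parent).
#' @export
standardize <- function(mol) {
  stopifnot(is_molecule(mol))
  mol <- keep_parent_fragment(mol)
  mol <- apply_protonation_rules(mol)
  mol$smiles <- canonical_key(mol)
  mol$rings <- NULL
  mol
}

# Largest fragment preferring carbon-containing ones; heavy-atom count
# breaks ties, then lowest fragment index (deterministic).
keep_parent_fragment <- function(mol) {
  comp <- fragment_ids(mol)
  if (length(unique(comp)) <= 1) return(mol)
  info <- tibble::tibble(
    frag = sort(unique(comp)),
    has_c = vapply(sort(unique(comp)), function(f)
      any(mol$atoms$element[comp == f] == "C"), logical(1)),
    n_heavy = vapply(sort(unique(comp)), function(f)
      sum(mol$atoms$element[comp == f] != "H"), integer(1)))
  info <- info[order(-info$has_c, -info$n_heavy, info$frag), ]
  keep <- which(comp == info$frag[1])
  subset_atoms(mol, keep)
}

# Restrict a molecule to a subset of atoms, remapping bonds/conformers.
subset_atoms <- function(mol, keep) {
  keep <- sort(keep)
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]
  bonds$j <- remap[bonds$j]
  molecule(mol$id, mol$atoms[keep, , drop = FALSE], bonds,
           conformers = lapply(mol$conformers, function(m) m[keep, , drop = FALSE]),
           properties = mol$properties, smiles = NA_character_)
}

apply_protonation_rules <- function(mol) {
  el <- mol$atoms$element
  adj <- adjacency(mol)
  arom <- aromatic_atoms(mol)
  nH <- hydrogen_count(mol)
  ord <- degree_order(mol)
  charge <- mol$atoms$charge

  bond_order_between <- function(i, j) {
    hit <- (mol$bonds$i == i & mol$bonds$j == j) |
      (mol$bonds$i == j & mol$bonds$j == i)
    if (any(hit)) mol$bonds$order[hit][1] else 0
  }
  has_double_O <- function(c_idx) {
    any(vapply(adj[[c_idx]], function(nb)
      el[nb] == "O" && bond_order_between(c_idx, nb) == 2, logical(1)))
  }

  for (a in seq_along(el)) {
    if (charge[a] != 0) next
    if (el[a] == "O" && nH[a] >= 1) {
      # acid O-H: attached to C(=O) or S(=O)(=O)
      for (nb in adj[[a]]) {
        if (el[nb] == "C" && has_double_O(nb)) { charge[a] <- -1L; break }
        if (el[nb] == "S" && sum(vapply(adj[[nb]], function(x)
          el[x] == "O" && bond_order_between(nb, x) == 2, logical(1))) >= 2) {
          charge[a] <- -1L; break
        }
      }
    } else if (el[a] == "N" && !arom[a]) {
      nbs <- adj[[a]]
      nb_heavy <- nbs[el[nbs] != "H"]
      adjacent_carbonyl <- any(vapply(nb_heavy, function(nb)
        el[nb] == "C" && has_double_O(nb), logical(1)))
      adjacent_aromatic <- any(arom[nb_heavy])
      if (ord[a] <= length(nbs) && max(c(0, vapply(nbs, function(nb)
        bond_order_between(a, nb), numeric(1)))) <= 1 &&
          !adjacent_carbonyl && !adjacent_aromatic && nH[a] + length(nb_heavy) <= 3 + 1) {
        # aliphatic amine (primary/secondary/tertiary)
        charge[a] <- 1L
      } else if (any(vapply(nbs, function(nb)
        el[nb] == "C" && bond_order_between(a, nb) == 2 &&
          any(el[adj[[nb]]] == "N" & adj[[nb]] != a), logical(1)))) {
        # amidine / guanidine =N- : protonate the imine nitrogen
        charge[a] <- 1L
      }
    }
  }
  mol$atoms$charge <- charge
  mol
}
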