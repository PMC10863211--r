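# Pose validation for type II kinase inhibitors: geometric hydrogen
# bond detection against named key residues (hinge cysteine, DFG
# aspartate, alpha-C glutamate), hydrophobic back-pocket contact
# counting, and Calpha superposition of kinase domains.

#' Read a target interaction specification
#'
#' YAML with `key_residues` (named residue triplets chain/resno/resid),
#' `back_pocket` (residue names counted for hydrophobic contacts),
#' `contact_dist`, `min_contacts` and `hbond` criteria. Specifications
#' for the VEGFR2 (Cys919/Asp1046/Glu885) and FAK (Cys502/Asp564/
#' Glu471) kinase domains ship with the package.
#'
#' @param target `"vegfr2"`, `"fak"`, or a path to a custom YAML file.
#' @return Named list.
#' @export
read_target_spec <- function(target) {
  path <- if (target %in% c("vegfr2", "fak")) {
    system.file("extdata", paste0("target_", target, ".yaml"),
                package = "pharmscreen")
  } else target
  yaml::read_yaml(path)
}

# Donor/acceptor typing for protein atoms by residue and atom name.
# Conservative: backbone N (with H) donates, backbone O accepts;
# side-chain O of Asp/Glu accepts, side-chain N-H of the common donors
# donates, hydroxyls do both.
protein_polar_atoms <- function(atoms) {
  elety <- trimws(atoms$elety)
  acceptors <- atoms$element == "O" |
    (atoms$element == "N" & atoms$resid %in% c("HIS") & elety %in% c("ND1", "NE2"))
  donors <- (elety == "N" & !atoms$het) |
    (atoms$element == "N" & elety %in% c("NE", "NH1", "NH2", "NZ", "ND2",
                                         "NE2", "NE1", "ND1")) |
    (atoms$element == "O" & elety %in% c("OG", "OG1", "OH"))
  list(donors = which(donors), acceptors = which(acceptors))
}

#' Detect hydrogen bonds between a ligand pose and named residues
#'
#' Geometric criterion: donor-acceptor heavy-atom distance at most
#' `d_max` and, where the donor hydrogen position is available, a
#' D-H...A angle of at least `angle_min` degrees. When no hydrogen is
#' present on a donor (apo heavy-atom structures), the angle criterion
#' is waived and the bond is reported with `angle = NA`.
#'
#' @param ligand A [molecule()] with one conformer in the protein frame
#'   (explicit polar hydrogens recommended).
#' @param protein A `ps_protein`.
#' @param residues Tibble or list of residue selectors with `chain`,
#'   `resno` and optionally `resid`.
#' @param d_max Maximum heavy-atom distance (Angstrom).
#' @param angle_min Minimum D-H...A angle (degrees).
#' @return Tibble: `residue`, `direction` (`"ligand_donor"` or
#'   `"protein_donor"`), `donor_atom`, `acceptor_atom`, `distance`,
#'   `angle`.
#' @export
detect_hbonds <- function(ligand, protein, residues, d_max = 3.5,
                          angle_min = 120) {
  stopifnot(is_molecule(ligand), inherits(protein, "ps_protein"))
  if (!length(ligand$conformers)) abort("ligand pose has no coordinates")
  if (is.data.frame(residues)) {
    residues <- lapply(seq_len(nrow(residues)), function(k) as.list(residues[k, ]))
  }
  lig_xyz <- ligand$conformers[[1]]
  el <- ligand$atoms$element
  adj <- adjacency(ligand)
  nH <- hydrogen_count(ligand)
  lig_acc <- which(el %in% c("N", "O"))
  lig_don <- which(el %in% c("N", "O") & nH >= 1)
  h_of <- function(a) adj[[a]][el[adj[[a]]] == "H"]

  out <- list()
  for (r in residues) {
    sel <- protein$atoms$resno == r$resno &
      (is.null(r$chain) | protein$atoms$chain == (r$chain %||% protein$atoms$chain))
    if (!is.null(r$resid)) sel <- sel & protein$atoms$resid == r$resid
    if (!any(sel)) {
      abort(sprintf("residue %s%s not found in structure",
                    r$resid %||% "", r$resno))
    }
    res_atoms <- protein$atoms[sel, ]
    res_tag <- sprintf("%s%d", res_atoms$resid[1], r$resno)
    pol <- protein_polar_atoms(res_atoms)
    rx <- as.matrix(res_atoms[, c("x", "y", "z")])

    # ligand donor -> protein acceptor
    for (a in lig_don) {
      for (pa in pol$acceptors) {
        dvec <- rx[pa, ] - lig_xyz[a, ]
        dd <- sqrt(sum(dvec^2))
        if (dd > d_max + 1e-9 || dd < 0.5) next
        hs <- h_of(a)
        ang <- if (length(hs)) {
          max(vapply(hs, function(h)
            hba_angle(lig_xyz[a, ], lig_xyz[h, ], rx[pa, ]), numeric(1)))
        } else NA_real_
        if (!is.na(ang) && ang < angle_min - 1e-9) next
        out[[length(out) + 1]] <- tibble::tibble(
          residue = res_tag, direction = "ligand_donor",
          donor_atom = sprintf("lig:%d", a),
          acceptor_atom = sprintf("%s:%s", res_tag, trimws(res_atoms$elety[pa])),
          distance = dd, angle = ang)
      }
    }
    # protein donor -> ligand acceptor (protein H positions rarely
    # present in crystal structures; angle waived when absent)
    ph <- which(res_atoms$element == "H")
    for (pd in pol$donors) {
      for (a in lig_acc) {
        dvec <- lig_xyz[a, ] - rx[pd, ]
        dd <- sqrt(sum(dvec^2))
        if (dd > d_max + 1e-9 || dd < 0.5) next
        ang <- NA_real_
        if (length(ph)) {
          hd <- ph[sqrt(rowSums(sweep(rx[ph, , drop = FALSE], 2, rx[pd, ])^2)) < 1.3]
          if (length(hd)) {
            ang <- max(vapply(hd, function(h)
              hba_angle(rx[pd, ], rx[h, ], lig_xyz[a, ]), numeric(1)))
          }
        }
        if (!is.na(ang) && ang < angle_min - 1e-9) next
        out[[length(out) + 1]] <- tibble::tibble(
          residue = res_tag, direction = "protein_donor",
          donor_atom = sprintf("%s:%s", res_tag, trimws(res_atoms$elety[pd])),
          acceptor_atom = sprintf("lig:%d", a),
          distance = dd, angle = ang)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(residue = character(), direction = character(),
                          donor_atom = character(), acceptor_atom = character(),
                          distance = numeric(), angle = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Validate the type II interaction pattern of a docked pose
#'
#' A pose passes when every configured key residue (hinge, DFG motif,
#' alpha-C glutamate) makes at least one qualifying hydrogen bond with
#' the ligand and the ligand makes at least `min_contacts` apolar
#' carbon-carbon contacts (within `contact_dist`) with back-pocket
#' residues.
#'
#' @param pose Ligand [molecule()] in the protein frame.
#' @param protein A `ps_protein`.
#' @param target_spec Specification from [read_target_spec()].
#' @return A `ph4_interactions` list: `per_residue` tibble (residue
#'   role, satisfied, best distance/angle), `contacts` count,
#'   `hbonds` (full table), `type2_pass`.
#' @export
validate_type2 <- function(pose, protein, target_spec) {
  spec <- target_spec
  crit <- spec$hbond %||% list(d_max = 3.5, angle_min = 120)
  res_list <- spec$key_residues
  hb <- detect_hbonds(pose, protein, unname(res_list),
                      d_max = crit$d_max, angle_min = crit$angle_min)
  per <- dplyr::bind_rows(lapply(names(res_list), function(role) {
    r <- res_list[[role]]
    tag <- sprintf("%s%d", r$resid, r$resno)
    rows <- hb[hb$residue == tag, ]
    tibble::tibble(role = role, residue = tag,
                   satisfied = nrow(rows) > 0,
                   distance = if (nrow(rows)) min(rows$distance) else NA_real_,
                   n_bonds = nrow(rows))
  }))
  # hydrophobic back-pocket contacts: ligand apolar C vs apolar C of
  # back-pocket residue types
  el <- pose$atoms$element
  adj <- adjacency(pose)
  apolar_lig <- which(el == "C" & !vapply(seq_along(el), function(a)
    any(el[adj[[a]]] %in% c("N", "O", "S", "P")), logical(1)))
  bp <- protein$atoms[!protein$atoms$het &
                        protein$atoms$resid %in% (spec$back_pocket$resids %||%
                                                    character(0)) &
                        protein$atoms$element == "C", ]
  n_contacts <- 0L
  if (nrow(bp) && length(apolar_lig)) {
    bx <- as.matrix(bp[, c("x", "y", "z")])
    lx <- pose$conformers[[1]][apolar_lig, , drop = FALSE]
    for (i in seq_len(nrow(lx))) {
      d <- sqrt(rowSums(sweep(bx, 2, lx[i, ])^2))
      n_contacts <- n_contacts + sum(d <= (spec$contact_dist %||% 4.5))
    }
  }
  pass <- all(per$satisfied) && n_contacts >= (spec$min_contacts %||% 3)
  structure(list(per_residue = per, contacts = n_contacts, hbonds = hb,
                 type2_pass = pass, target = spec$name %||% ""),
            class = "ph4_interactions")
}

#' @export
print.ph4_interactions <- function(x, ...) {
  cat(sprintf("<ph4_interactions> %s: %s (%d back-pocket contacts)\n",
              x$target, if (x$type2_pass) "type II pattern satisfied"
              else "type II pattern NOT satisfied", x$contacts))
  print(x$per_residue)
  invisible(x)
}

#' Superpose two protein structures on aligned Calpha pairs
#'
#' @param prot_a,prot_b `ps_protein` objects.
#' @param pair_alignment Tibble with columns `resno_a`, `resno_b` (and
#'   optional `chain_a`, `chain_b`) mapping residues of A onto B, e.g.
#'   derived from a sequence alignment.
#' @return List: `transform` (moves A onto B), `ca_rmsd` (Angstrom),
#'   `n_pairs`, and `pairs` (the residue pairs used).
#' @export
superpose <- function(prot_a, prot_b, pair_alignment) {
  pa <- tibble::as_tibble(pair_alignment)
  if (nrow(pa) < 3) abort("need at least 3 aligned residue pairs")
  ca_of <- function(prot, resno, chain = NA) {
    sel <- trimws(prot$atoms$elety) == "CA" & prot$atoms$resno == resno & !prot$atoms$het
    if (!is.na(chain)) sel <- sel & prot$atoms$chain == chain
    w <- which(sel)
    if (!length(w)) return(c(NA_real_, NA_real_, NA_real_))
    unlist(prot$atoms[w[1], c("x", "y", "z")], use.names = FALSE)
  }
  chain_a <- if ("chain_a" %in% names(pa)) pa$chain_a else rep(NA, nrow(pa))
  chain_b <- if ("chain_b" %in% names(pa)) pa$chain_b else rep(NA, nrow(pa))
  A <- t(vapply(seq_len(nrow(pa)), function(k)
    ca_of(prot_a, pa$resno_a[k], chain_a[k]), numeric(3)))
  B <- t(vapply(seq_len(nrow(pa)), function(k)
    ca_of(prot_b, pa$resno_b[k], chain_b[k]), numeric(3)))
  ok <- stats::complete.cases(A) & stats::complete.cases(B)
  if (sum(ok) < 3) abort("fewer than 3 resolvable Calpha pairs")
  fit <- kabsch(A[ok, , drop = FALSE], B[ok, , drop = FALSE])
  list(transform = fit[c("rotation", "translation")],
       ca_rmsd = fit$rmsd, n_pairs = sum(ok), pairs = pa[ok, , drop = FALSE])
}
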