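# Seeded generators for every input the pipeline needs: planted
# feature-cloud libraries for the matcher, Bernoulli confusion
# libraries for the metric battery, toy protein-ligand complexes for
# the interaction validator, and planned-violation descriptor libraries
# for the filtration cascade.  All generators restore the caller's RNG
# state and are field-identical when re-run with the same seed.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a planted active/decoy feature-cloud library
#'
#' Actives are the model's feature centers perturbed by isotropic
#' Gaussian noise, rigidly transformed at random, and padded with
#' distractor points placed in sterically allowed space (outside the
#' model's excluded volumes in the model frame, so a correct match is
#' never blocked by construction). Decoys either keep the correct
#' feature-kind multiset with fully shuffled geometry, or delete one
#' essential feature from an otherwise active-like cloud (50/50). The
#' decoy:active ratio defaults to the ~30:1 shape of kinase screening
#' test sets.
#'
#' @param model A [ph4_model()].
#' @param n_active,n_decoy Library composition (defaults 40/1200, the
#'   shape of the larger published kinase test set).
#' @param noise_sd Isotropic per-coordinate noise, Angstrom.
#' @param seed Integer seed.
#' @param n_distractors Distractor points added to every active.
#' @param prefix Identifier prefix.
#' @return List: `features` (named list of `ph4_features`), `labels`
#'   (activity records: actives with IC50 below the 10 uM cutoff,
#'   decoys unlabelled), `truth` (per-molecule: `is_active`, decoy
#'   variant, and for actives the RMSD of the true planted
#'   correspondence after least-squares fit), `noise_sd`, `seed`.
#' @export
gen_feature_fixtures <- function(model, n_active = 40, n_decoy = 1200,
                                 noise_sd = 0.2, seed = 1,
                                 n_distractors = 2, prefix = "fix") {
  stopifnot(is_ph4_model(model), noise_sd >= 0)
  feats <- model$features
  ess_idx <- which(feats$essential)
  centers <- as.matrix(feats[, c("x", "y", "z")])
  box_lo <- apply(centers, 2, min) - 2
  box_hi <- apply(centers, 2, max) + 2
  ex <- model$exclusions
  ecoord <- if (nrow(ex)) as.matrix(ex[, c("x", "y", "z")]) else NULL

  free_point <- function() {
    for (try in 1:80) {
      p <- runif(3, box_lo, box_hi)
      if (is.null(ecoord)) return(p)
      d <- sqrt(rowSums(sweep(ecoord, 2, p)^2))
      if (all(d > ex$radius + 0.3)) return(p)
    }
    NULL
  }

  with_seed(seed, {
    features <- list()
    truth <- list()
    labels <- list()

    for (i in seq_len(n_active)) {
      id <- sprintf("%s_act%04d", prefix, i)
      noisy <- centers + matrix(rnorm(length(centers), 0, noise_sd),
                                nrow(centers), 3)
      true_rmsd <- kabsch(noisy[ess_idx, , drop = FALSE],
                          centers[ess_idx, , drop = FALSE])$rmsd
      kinds <- feats$kind
      pts <- noisy
      for (dd in seq_len(n_distractors)) {
        p <- free_point()
        if (is.null(p)) next
        kinds <- c(kinds, sample(FEATURE_KINDS, 1))
        pts <- rbind(pts, p)
      }
      tf <- random_rigid_transform(span = 15)
      pts <- apply_transform(pts, tf)
      features[[id]] <- feature_set(kinds, pts, molecule_id = id)
      truth[[id]] <- tibble::tibble(id = id, is_active = TRUE,
                                    variant = "active", true_rmsd = true_rmsd)
      labels[[id]] <- tibble::tibble(id = id,
                                     ic50 = 10^runif(1, 0.5, 3.95),
                                     label = "active")
    }

    for (i in seq_len(n_decoy)) {
      id <- sprintf("%s_dec%04d", prefix, i)
      drop_essential <- runif(1) < 0.5
      if (drop_essential) {
        keep <- setdiff(seq_len(nrow(feats)),
                        sample(ess_idx, 1))
        kinds <- feats$kind[keep]
        pts <- centers[keep, , drop = FALSE] +
          matrix(rnorm(3 * length(keep), 0, max(noise_sd, 0.05)),
                 length(keep), 3)
        variant <- "missing_essential"
      } else {
        kinds <- feats$kind
        pts <- t(replicate(length(kinds), runif(3, box_lo, box_hi)))
        variant <- "shuffled_geometry"
      }
      tf <- random_rigid_transform(span = 15)
      pts <- apply_transform(pts, tf)
      features[[id]] <- feature_set(kinds, pts, molecule_id = id)
      truth[[id]] <- tibble::tibble(id = id, is_active = FALSE,
                                    variant = variant, true_rmsd = NA_real_)
      labels[[id]] <- tibble::tibble(id = id, ic50 = NA_real_, label = "decoy")
    }

    list(features = features,
         labels = dplyr::bind_rows(labels),
         truth = dplyr::bind_rows(truth),
         noise_sd = noise_sd, seed = seed, model = model$name)
  })
}

#' Generate a Bernoulli hit/label library with target rates
#'
#' Assigns each active a hit with probability `target_se` and each
#' decoy with probability `1 - target_sp`, so the expected sensitivity
#' and specificity of the realized confusion matrix equal the targets.
#'
#' @param n_active,n_decoy Library composition.
#' @param target_se,target_sp Target rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `hits` (character ids), `labels` (activity records),
#'   `counts` (realized confusion matrix, one-row tibble).
#' @export
gen_confusion_library <- function(n_active, n_decoy, target_se, target_sp,
                                  seed = 1) {
  stopifnot(target_se >= 0, target_se <= 1, target_sp >= 0, target_sp <= 1)
  with_seed(seed, {
    act <- sprintf("act%05d", seq_len(n_active))
    dec <- sprintf("dec%05d", seq_len(n_decoy))
    hit_a <- runif(n_active) < target_se
    hit_d <- runif(n_decoy) < (1 - target_sp)
    labels <- tibble::tibble(
      id = c(act, dec),
      ic50 = NA_real_,
      label = c(rep("active", n_active), rep("decoy", n_decoy)))
    hits <- c(act[hit_a], dec[hit_d])
    list(hits = hits, labels = labels,
         counts = tibble::tibble(tp = sum(hit_a), fp = sum(hit_d),
                                 tn = sum(!hit_d), fn = sum(!hit_a)))
  })
}

#' Generate a toy kinase-site complex with controlled geometry
#'
#' Builds a minimal three-key-residue "protein" (hinge cysteine, DFG
#' aspartate, alpha-C glutamate, using the FAK numbering Cys502 /
#' Asp564 / Glu471, plus a leucine-like back pocket) and a ligand
#' placed so that every key hydrogen bond has heavy-atom distance
#' `d_hbond` and D-H...A angle `angle`, and the apolar ligand carbons
#' make `n_contacts` back-pocket contacts. The expected validator
#' verdict is returned as ground truth.
#'
#' @param d_hbond Donor-acceptor heavy-atom distance (Angstrom; > 0).
#' @param angle D-H...A angle in degrees (0 < angle <= 180).
#' @param n_contacts Planted back-pocket carbon contacts.
#' @param seed Integer seed (orientation jitter of the back pocket).
#' @param criteria H-bond criteria the truth verdict is computed
#'   against (`d_max`, `angle_min`, `min_contacts`).
#' @return List: `protein` (`ps_protein`), `ligand` (`ps_mol` pose),
#'   `truth` (list with `expected_pass` and the parameters).
#' @export
gen_toy_complex <- function(d_hbond = 2.9, angle = 170, n_contacts = 5,
                            seed = 1,
                            criteria = list(d_max = 3.5, angle_min = 120,
                                            min_contacts = 3)) {
  if (d_hbond <= 0 || angle <= 0 || angle > 180) {
    abort("impossible geometry: need d_hbond > 0 and 0 < angle <= 180")
  }
  th <- angle * pi / 180
  disc <- cos(th)^2 - 1 + d_hbond^2
  if (disc < 0) abort("impossible geometry: angle unreachable at this distance")
  # place H between donor D and acceptor A (|DH| = 1) such that the
  # D-H...A angle equals `angle`; law of cosines gives |HA| and the
  # off-axis angle beta at D
  ha <- cos(th) + sqrt(disc)
  cos_beta <- (1 + d_hbond^2 - ha^2) / (2 * d_hbond)
  beta <- acos(pmin(1, pmax(-1, cos_beta)))
  h_offset <- function(axis) {
    # unit vector at angle beta from `axis` (in a fixed perpendicular plane)
    perp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * axis) * axis
    perp <- perp / sqrt(sum(perp^2))
    cos(beta) * axis + sin(beta) * perp
  }

  with_seed(seed, {
    # --- protein scaffold -------------------------------------------------
    prot <- list()
    addp <- function(resid, resno, elety, element, pos, het = FALSE) {
      prot[[length(prot) + 1]] <<- tibble::tibble(
        chain = "A", resno = resno, ins = "", resid = resid,
        elety = elety, element = element,
        x = pos[1], y = pos[2], z = pos[3], het = het)
    }
    # hinge Cys502: backbone N-H donating toward the ligand acceptor
    cys_n <- c(0, 0, 0)
    axis1 <- c(1, 0, 0)                       # toward ligand acceptor
    addp("CYS", 502, "N", "N", cys_n)
    addp("CYS", 502, "H", "H", cys_n + h_offset(axis1))
    addp("CYS", 502, "CA", "C", cys_n + c(-1.2, 0.9, 0))
    addp("CYS", 502, "C", "C", cys_n + c(-2.5, 0.2, 0.4))
    addp("CYS", 502, "O", "O", cys_n + c(-3.4, 0.9, 0.4))
    lig_acc <- cys_n + axis1 * d_hbond

    # DFG Asp564: side-chain OD1 accepting from a ligand donor
    asp_od1 <- c(0, 9, 0)
    addp("ASP", 564, "CB", "C", asp_od1 + c(-1.0, 1.2, 0))
    addp("ASP", 564, "CG", "C", asp_od1 + c(-0.4, 0.9, 0.8))
    addp("ASP", 564, "OD1", "O", asp_od1)
    addp("ASP", 564, "OD2", "O", asp_od1 + c(0.6, 1.8, 1.2))
    axis2 <- c(0, -1, 0)                      # acceptor -> ligand donor
    lig_don1 <- asp_od1 + axis2 * d_hbond
    lig_h1 <- lig_don1 + h_offset(-axis2)

    # alpha-C Glu471: side-chain OE1 accepting from a second ligand donor
    glu_oe1 <- c(0, 0, 9)
    addp("GLU", 471, "CD", "C", glu_oe1 + c(-0.8, 0.6, 1.0))
    addp("GLU", 471, "OE1", "O", glu_oe1)
    addp("GLU", 471, "OE2", "O", glu_oe1 + c(0.9, 0.9, 1.5))
    axis3 <- c(0, 0, -1)
    lig_don2 <- glu_oe1 + axis3 * d_hbond
    lig_h2 <- lig_don2 + h_offset(-axis3)

    # back pocket: leucine-like carbons around the apolar ligand group
    lig_c1 <- c(5, 4, 4)
    lig_c2 <- lig_c1 + c(1.5, 0, 0)
    lig_c3 <- lig_c1 + c(0, 1.5, 0)
    if (n_contacts > 0) {
      for (k in seq_len(n_contacts)) {
        phi <- 2 * pi * k / max(1, n_contacts) + runif(1, -0.1, 0.1)
        pos <- lig_c1 + 4.0 * c(cos(phi) * 0.0, sin(phi), cos(phi)) /
          sqrt(sum(c(0, sin(phi), cos(phi))^2))
        addp("LEU", 567, sprintf("CD%d", k), "C", pos)
      }
    }
    protein <- new_protein(dplyr::bind_rows(prot), source = "gen_toy_complex")

    # --- ligand pose ------------------------------------------------------
    lig_atoms <- tibble::tibble(
      element = c("O", "N", "H", "N", "H", "C", "C", "C"),
      charge = 0L)
    lig_coords <- rbind(lig_acc, lig_don1, lig_h1, lig_don2, lig_h2,
                        lig_c1, lig_c2, lig_c3)
    lig_bonds <- tibble::tibble(i = c(2L, 4L, 6L, 6L),
                                j = c(3L, 5L, 7L, 8L),
                                order = 1)
    ligand <- molecule("toy_ligand", lig_atoms, lig_bonds,
                       conformers = list(conf1 = unname(lig_coords)))

    # ground truth: count contacts exactly as the validator defines them
    bp <- rbind(lig_c1, lig_c2, lig_c3)
    prot_bp <- protein$atoms[protein$atoms$resid == "LEU" &
                               protein$atoms$element == "C", ]
    n_real <- 0L
    if (nrow(prot_bp)) {
      bx <- as.matrix(prot_bp[, c("x", "y", "z")])
      for (i in seq_len(nrow(bp))) {
        n_real <- n_real + sum(sqrt(rowSums(sweep(bx, 2, bp[i, ])^2)) <= 4.5)
      }
    }
    expected <- d_hbond <= criteria$d_max && angle >= criteria$angle_min &&
      n_real >= criteria$min_contacts
    list(protein = protein, ligand = ligand,
         truth = list(expected_pass = expected, d_hbond = d_hbond,
                      angle = angle, n_contacts_planted = n_contacts,
                      n_contacts_real = n_real))
  })
}

#' Generate a planned-violation descriptor library
#'
#' Draws descriptor rows inside "clean" ranges (every cascade stage
#' passes), then perturbs each molecule according to its violation
#' plan so it is removed at exactly the planned stage of the default
#' cascade. Supported plan values: `clean`, `dedup`, `window`,
#' `lipinski`, `veber`, `mutagenic`, `logs`, `oprea`, `pains`.
#'
#' @param n Library size (ignored when `violation_plan` is a vector).
#' @param violation_plan Character vector of plan values (recycled to
#'   `n`), or `NULL` for all clean.
#' @param descriptor_ranges Named list of `c(min, max)` clean ranges to
#'   override the defaults (`mw`, `clogp`, `tpsa`, `logs`).
#' @param seed Integer seed.
#' @return Tibble usable by [apply_cascade()]: descriptors plus
#'   `pains_n`, `mutagenic_n` and the bookkeeping column `planned`.
#' @export
gen_property_library <- function(n = 100, violation_plan = NULL,
                                 descriptor_ranges = NULL, seed = 1) {
  # clean ranges sit inside every stage's bounds, including the
  # lead-like mw <= 450
  defaults <- list(mw = c(355, 448), clogp = c(0, 4), tpsa = c(40, 120),
                   logs = c(-4.5, -1))
  ranges <- utils::modifyList(defaults, descriptor_ranges %||% list())
  for (nm in names(ranges)) {
    if (ranges[[nm]][1] > ranges[[nm]][2]) {
      abort(sprintf("unattainable plan: empty %s range", nm))
    }
  }
  if (ranges$mw[2] < 150) {
    abort("unattainable plan: molecular weight range too low for a lead-like library")
  }
  plan <- violation_plan %||% rep("clean", n)
  plan <- rep_len(plan, max(n, length(violation_plan %||% character(0))))
  known <- c("clean", "dedup", "window", "lipinski", "veber", "mutagenic",
             "logs", "oprea", "pains")
  bad <- setdiff(plan, known)
  if (length(bad)) abort(sprintf("unknown violation plan value '%s'", bad[1]))

  with_seed(seed, {
    n <- length(plan)
    d <- tibble::tibble(
      id = sprintf("syn%05d", seq_len(n)),
      key = sprintf("syn%05d", seq_len(n)),
      mw = runif(n, ranges$mw[1], ranges$mw[2]),
      clogp = runif(n, ranges$clogp[1], ranges$clogp[2]),
      tpsa = runif(n, ranges$tpsa[1], ranges$tpsa[2]),
      hbd = sample(0:4, n, replace = TRUE),
      hba = sample(2:8, n, replace = TRUE),
      rotb = sample(0:8, n, replace = TRUE),
      rings = sample(1:4, n, replace = TRUE),
      aromatic_fraction = runif(n, 0.2, 0.6),
      logs = runif(n, ranges$logs[1], ranges$logs[2]),
      pains_n = 0L, mutagenic_n = 0L,
      planned = plan)
    d$wlogp <- d$clogp
    clean_ids <- which(plan == "clean")
    for (k in seq_len(n)) {
      d[k, ] <- switch(plan[k],
        clean = d[k, ],
        dedup = {
          row <- d[k, ]
          # duplicate an *earlier* row so the dedup stage removes this
          # one (first occurrence wins), keeping bookkeeping exact
          earlier <- clean_ids[clean_ids < k]
          if (!length(earlier) && k == 1) {
            abort("unattainable plan: a dedup row needs an earlier row to duplicate")
          }
          row$key <- d$key[if (length(earlier)) earlier[1] else k - 1L]
          row
        },
        window = { row <- d[k, ]; row$mw <- runif(1, 200, 340); row },
        lipinski = {  # two violations, still inside the 350-500 window
          row <- d[k, ]; row$mw <- 500; row$clogp <- runif(1, 5.1, 6)
          row$wlogp <- row$clogp; row
        },
        veber = { row <- d[k, ]; row$tpsa <- runif(1, 145, 200); row },
        mutagenic = { row <- d[k, ]; row$mutagenic_n <- 1L; row },
        logs = { row <- d[k, ]; row$logs <- runif(1, -8, -5.5); row },
        oprea = { row <- d[k, ]; row$rings <- sample(5:7, 1); row },
        pains = { row <- d[k, ]; row$pains_n <- 1L; row })
    }
    d
  })
}

#' Generate a small organic library as SMILES-derived molecules
#'
#' Assembles simple aromatic/aliphatic SMILES from a fragment grammar;
#' used for round-trip and descriptor cross-check tests.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param tag Add an SD-style property to each molecule.
#' @return List of `ps_mol`.
#' @export
gen_molecule_library <- function(n = 20, seed = 1, tag = TRUE) {
  cores <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1",
             "c1ccsc1", "C1CCNCC1")
  linkers <- c("CC", "CCC", "C(=O)N", "CCO", "C(=O)O", "CN", "COC", "CS")
  caps <- c("C", "CC", "O", "N", "Cl", "C(F)(F)F", "C(C)C", "OC")
  with_seed(seed, {
    smi <- vapply(seq_len(n), function(k) {
      paste0(sample(cores, 1), sample(linkers, 1), sample(caps, 1))
    }, character(1))
    mols <- parse_smiles(smi, ids = sprintf("lib%03d", seq_len(n)))
    if (tag) {
      for (k in seq_along(mols)) {
        mols[[k]]$properties$source <- "fragment_grammar"
        mols[[k]]$properties$index <- as.character(k)
      }
    }
    mols
  })
}

#' Generate salt-form molecules for standardization tests
#'
#' Acid/base parents paired with counterions, e.g.
#' `CC(=O)[O-].[Na+]`; every output is multi-fragment by construction.
#'
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return List of `ps_mol`.
#' @export
gen_salt_library <- function(n = 20, seed = 1) {
  acids <- c("CC(=O)O", "CCC(=O)O", "c1ccccc1C(=O)O", "CC(C)C(=O)O",
             "CCS(=O)(=O)O")
  bases <- c("CCN", "CCCN", "CCNCC", "C1CCNCC1", "CN(C)C")
  with_seed(seed, {
    smi <- vapply(seq_len(n), function(k) {
      if (k %% 2 == 0) {
        paste0(sub("O$", "[O-]", sample(acids, 1)), ".[Na+]")
      } else {
        paste0(sample(bases, 1), ".Cl")
      }
    }, character(1))
    parse_smiles(smi, ids = sprintf("salt%03d", seq_len(n)))
  })
}
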