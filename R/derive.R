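# Receptor-based model derivation: shared protein-ligand interactions
# across a set of pre-superposed complexes become pharmacophore
# features; binding-site heavy atoms become excluded volumes.

#' Derive a pharmacophore model from aligned complexes
#'
#' For each complex, ligand-side interaction points are detected:
#' hydrogen-bond acceptors (ligand N/O near a protein donor), donors
#' (ligand N-H/O-H near a protein acceptor, with a projected point
#' toward the protein acceptor), hydrophobic group centroids in apolar
#' contact with the protein, and aromatic ring centroids buried in the
#' site. Points are clustered across complexes (single linkage,
#' `cluster_dist`); every cluster present in at least `min_share` of
#' the complexes becomes a feature (essential when shared by all,
#' optional otherwise; if fewer than three clusters are fully shared,
#' the three widest-shared become essential so the model stays
#' matchable). Every binding-site heavy atom within `site_radius` of
#' any ligand atom contributes an excluded-volume sphere.
#'
#' @param complexes List of `list(protein = ps_protein, ligand =
#'   ps_mol)` in a common (pre-superposed) frame.
#' @param min_share Minimum fraction of complexes sharing a cluster.
#' @param cluster_dist Single-linkage cut distance (Angstrom).
#' @param hbond_criteria List with `d_max` (heavy-atom distance).
#' @param exclusion_radius,site_radius Excluded-volume sphere radius
#'   and binding-site cutoff (Angstrom).
#' @param feature_radius Radius assigned to derived features.
#' @param name Model name.
#' @return A [ph4_model()].
#' @export
derive_model <- function(complexes, min_share = 0.5, cluster_dist = 2.0,
                         hbond_criteria = list(d_max = 3.5),
                         exclusion_radius = 1.2, site_radius = 8,
                         feature_radius = 1.0, name = "derived") {
  if (length(complexes) < 2) abort("need at least 2 complexes")
  pts <- dplyr::bind_rows(lapply(seq_along(complexes), function(k) {
    cx <- complexes[[k]]
    p <- interaction_points(cx$ligand, cx$protein, hbond_criteria$d_max %||% 3.5)
    if (nrow(p)) p$complex <- k
    p
  }))
  if (!nrow(pts)) abort("no protein-ligand interactions detected")

  n_cx <- length(complexes)
  feats <- list()
  for (kind in unique(pts$kind)) {
    sub <- pts[pts$kind == kind, , drop = FALSE]
    cl <- if (nrow(sub) == 1) 1L else {
      stats::cutree(stats::hclust(stats::dist(sub[, c("x", "y", "z")]),
                                  method = "single"), h = cluster_dist)
    }
    for (g in unique(cl)) {
      rows <- sub[cl == g, , drop = FALSE]
      share <- length(unique(rows$complex)) / n_cx
      if (share < min_share) next
      feats[[length(feats) + 1]] <- tibble::tibble(
        kind = kind,
        x = mean(rows$x), y = mean(rows$y), z = mean(rows$z),
        share = share, annotation = rows$annotation[1])
    }
  }
  if (!length(feats)) {
    abort(sprintf("empty model: no interaction shared by >= %.0f%% of complexes",
                  100 * min_share))
  }
  feats <- dplyr::bind_rows(feats)
  feats <- feats[order(-feats$share, match(feats$kind, FEATURE_KINDS)), ]
  feats$essential <- feats$share >= 1
  if (sum(feats$essential) < 3) {
    feats$essential[seq_len(min(3, nrow(feats)))] <- TRUE
  }
  if (sum(feats$essential) < 3) {
    abort("empty-model error: fewer than 3 shareable features")
  }
  feats$label <- paste0("F", seq_len(nrow(feats)), ":", feats$kind)

  excl <- dplyr::bind_rows(lapply(complexes, function(cx) {
    lig_xyz <- cx$ligand$conformers[[1]]
    pa <- cx$protein$atoms[!cx$protein$atoms$het &
                             cx$protein$atoms$element != "H", ]
    px <- as.matrix(pa[, c("x", "y", "z")])
    near <- vapply(seq_len(nrow(px)), function(i)
      min(sqrt(rowSums(sweep(lig_xyz, 2, px[i, ])^2))) <= site_radius,
      logical(1))
    tibble::tibble(x = px[near, 1], y = px[near, 2], z = px[near, 3],
                   radius = exclusion_radius)
  }))
  excl <- excl[!duplicated(round(excl[, c("x", "y", "z")], 6)), , drop = FALSE]
  # an excluded volume overlapping a feature center would veto every
  # correctly mapped pose; receptor atoms that close to a feature
  # (e.g. the acceptor behind a projected donor) are skipped
  if (nrow(excl)) {
    fcen <- as.matrix(feats[, c("x", "y", "z")])
    keep <- vapply(seq_len(nrow(excl)), function(i) {
      min(sqrt(rowSums(sweep(fcen, 2,
                             c(excl$x[i], excl$y[i], excl$z[i]))^2))) >
        excl$radius[i] + 0.5
    }, logical(1))
    excl <- excl[keep, , drop = FALSE]
  }

  ph4_model(name,
            tibble::tibble(label = feats$label, kind = feats$kind,
                           x = feats$x, y = feats$y, z = feats$z,
                           radius = feature_radius,
                           essential = feats$essential,
                           annotation = feats$annotation),
            excl,
            provenance = sprintf("derived from %d complexes (min_share %.2f)",
                                 n_cx, min_share))
}

# Ligand-side interaction points of a single complex.
interaction_points <- function(ligand, protein, d_max = 3.5,
                               contact_dist = 4.5, proj_dist = 2.8) {
  stopifnot(is_molecule(ligand), inherits(protein, "ps_protein"))
  if (!length(ligand$conformers)) abort("ligand has no pose coordinates")
  lx <- ligand$conformers[[1]]
  el <- ligand$atoms$element
  adj <- adjacency(ligand)
  nH <- hydrogen_count(ligand)
  pa <- protein$atoms[!protein$atoms$het, ]
  pol <- protein_polar_atoms(pa)
  px <- as.matrix(pa[, c("x", "y", "z")])
  res_tag <- sprintf("%s%d", pa$resid, pa$resno)

  nearest <- function(pos, idx) {
    if (!length(idx)) return(NULL)
    d <- sqrt(rowSums(sweep(px[idx, , drop = FALSE], 2, pos)^2))
    list(i = idx[which.min(d)], d = min(d))
  }
  out <- list()
  add <- function(kind, pos, annotation) {
    out[[length(out) + 1]] <<- tibble::tibble(
      kind = kind, x = pos[1], y = pos[2], z = pos[3], annotation = annotation)
  }
  for (a in which(el %in% c("N", "O"))) {
    hit <- nearest(lx[a, ], pol$donors)
    if (!is.null(hit) && hit$d <= d_max) {
      add("ACC", lx[a, ], paste("near", res_tag[hit$i]))
    }
    if (nH[a] >= 1) {
      hit <- nearest(lx[a, ], pol$acceptors)
      if (!is.null(hit) && hit$d <= d_max) {
        add("DON", lx[a, ], paste("toward", res_tag[hit$i]))
        v <- px[hit$i, ] - lx[a, ]
        proj <- lx[a, ] + v / sqrt(sum(v^2)) * proj_dist
        add("DON_PROJ", proj, paste("toward", res_tag[hit$i]))
      }
    }
  }
  if (nrow(ligand$bonds)) {
    apolar <- el == "C" & !vapply(seq_along(el), function(a)
      any(el[adj[[a]]] %in% c("N", "O", "S", "P")), logical(1))
    prot_c <- which(pa$element == "C")
    for (g in apolar_components(adj, apolar)) {
      if (length(g) < 3) next
      centroid <- colMeans(lx[g, , drop = FALSE])
      hit <- nearest(centroid, prot_c)
      if (!is.null(hit) && hit$d <= contact_dist + 1) {
        add("HYD", centroid, paste("contacting", res_tag[hit$i]))
      }
    }
    ri <- perceive_rings(ligand)
    for (k in seq_along(ri$rings)) {
      if (!isTRUE(ri$aromatic[k])) next
      centroid <- colMeans(lx[ri$rings[[k]], , drop = FALSE])
      hit <- nearest(centroid, prot_c)
      if (!is.null(hit) && hit$d <= contact_dist + 1.5) {
        add("ARO", centroid, paste("stacked on", res_tag[hit$i]))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(kind = character(), x = numeric(), y = numeric(),
                          z = numeric(), annotation = character()))
  }
  dplyr::bind_rows(out)
}
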