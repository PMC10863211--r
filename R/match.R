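# The pharmacophore matching engine: type/distance prefilter over
# feature correspondences, least-squares alignment (Kabsch) as fitness,
# and an excluded-volume clash check on the aligned pose.

#' Enumerate candidate feature correspondences
#'
#' Finds every assignment of the model's essential features to distinct
#' conformer points of identical kind such that all pairwise distances
#' agree with the model's inter-feature distances within `pair_tol`
#' (the distance-similarity prefilter). Optional (non-essential)
#' features are appended greedily where a compatible unused point
#' exists. Output order is deterministic (depth-first over ascending
#' point indices).
#'
#' @param fs A `ph4_features` tibble ([feature_set()] or
#'   [perceive_features()]).
#' @param model A [ph4_model()].
#' @param pair_tol Pairwise distance tolerance in Angstrom.
#' @return List of candidate mappings, each a list with integer vectors
#'   `essential` and `optional` (point row indices named by feature
#'   label). Empty list when no candidate exists.
#' @export
enumerate_correspondences <- function(fs, model, pair_tol = 1.0) {
  stopifnot(is_ph4_model(model), pair_tol > 0)
  ess <- which(model$features$essential)
  opt <- which(!model$features$essential)
  fcoord <- as.matrix(model$features[, c("x", "y", "z")])
  pcoord <- feature_coords(fs)
  fdist <- as.matrix(stats::dist(fcoord))
  pdist <- if (nrow(fs)) as.matrix(stats::dist(pcoord)) else
    matrix(0, 0, 0)
  cand_pts <- lapply(ess, function(f) which(fs$kind == model$features$kind[f]))
  if (any(vapply(cand_pts, length, integer(1)) == 0)) return(list())

  results <- list()
  k <- length(ess)
  assign_next <- function(depth, chosen) {
    if (depth > k) {
      results[[length(results) + 1]] <<- chosen
      return(invisible())
    }
    for (p in cand_pts[[depth]]) {
      if (p %in% chosen) next
      ok <- TRUE
      for (d in seq_len(depth - 1)) {
        if (abs(pdist[p, chosen[d]] - fdist[ess[depth], ess[d]]) > pair_tol) {
          ok <- FALSE; break
        }
      }
      if (ok) assign_next(depth + 1, c(chosen, p))
    }
  }
  assign_next(1L, integer(0))
  lapply(results, function(chosen) {
    essential <- setNames(chosen, model$features$label[ess])
    optional <- integer(0)
    used <- chosen
    used_feats <- ess
    for (f in opt) {
      pts <- setdiff(which(fs$kind == model$features$kind[f]), used)
      best <- NA_integer_; best_dev <- Inf
      for (p in pts) {
        devs <- abs(pdist[p, used] - fdist[f, used_feats])
        if (all(devs <= pair_tol) && max(devs) < best_dev) {
          best <- p; best_dev <- max(devs)
        }
      }
      if (!is.na(best)) {
        optional <- c(optional, setNames(best, model$features$label[f]))
        used <- c(used, best)
        used_feats <- c(used_feats, f)
      }
    }
    list(essential = essential, optional = optional)
  })
}

#' Align a mapped conformer onto the model and score the fit
#'
#' Least-squares rigid superposition ([kabsch()]) of the mapped
#' conformer points onto the model's essential feature centers; the
#' fitness is the RMSD over the essential pairs (matched optional
#' features are reported but do not enter the score).
#'
#' @param fs A `ph4_features` tibble.
#' @param mapping One candidate from [enumerate_correspondences()].
#' @param model A [ph4_model()].
#' @return List with `transform` (rotation + translation moving the
#'   conformer into the model frame) and `rmsd` (Angstrom).
#' @export
align_and_score <- function(fs, mapping, model) {
  ess <- which(model$features$essential)
  if (length(mapping$essential) < 3) abort("mapping needs >= 3 pairs")
  p <- feature_coords(fs)[mapping$essential, , drop = FALSE]
  q <- as.matrix(model$features[ess, c("x", "y", "z")])
  if (collinearity_gap(p) < 1e-8 || collinearity_gap(q) < 1e-8) {
    abort(sprintf("degenerate (collinear) point set for mapping [%s]",
                  paste(names(mapping$essential), collapse = ", ")))
  }
  fit <- kabsch(p, q)
  list(transform = fit[c("rotation", "translation")], rmsd = fit$rmsd)
}

#' Excluded-volume clash check
#'
#' Tests whether any transformed heavy-atom center (or, for pure
#' feature-cloud fixtures, any feature point) lies strictly inside an
#' excluded-volume sphere of the model.
#'
#' @param coords n x 3 matrix of positions in the conformer frame.
#' @param transform Transform from [align_and_score()].
#' @param model A [ph4_model()].
#' @return List with `pass` (logical) and `clashes` (tibble: point
#'   index, sphere index, penetration depth in Angstrom).
#' @export
check_exclusions <- function(coords, transform, model) {
  stopifnot(is_ph4_model(model))
  ex <- model$exclusions
  if (!nrow(ex) || !nrow(coords)) {
    return(list(pass = TRUE, clashes = tibble::tibble(
      point = integer(), sphere = integer(), depth = numeric())))
  }
  moved <- apply_transform(coords, transform)
  ecoord <- as.matrix(ex[, c("x", "y", "z")])
  clashes <- list()
  for (s in seq_len(nrow(ex))) {
    d <- sqrt(rowSums(sweep(moved, 2, ecoord[s, ])^2))
    inside <- which(d < ex$radius[s] - 1e-12)
    if (length(inside)) {
      clashes[[length(clashes) + 1]] <- tibble::tibble(
        point = inside, sphere = s, depth = ex$radius[s] - d[inside])
    }
  }
  clashes <- if (length(clashes)) dplyr::bind_rows(clashes) else
    tibble::tibble(point = integer(), sphere = integer(), depth = numeric())
  list(pass = nrow(clashes) == 0, clashes = clashes)
}

#' Match a molecule or feature set against a pharmacophore model
#'
#' The full engine: for every conformer (or the supplied feature set),
#' enumerate type- and distance-compatible correspondences, align each
#' by least squares, discard poses above the RMSD cutoff or clashing
#' with an excluded volume, and report the best surviving candidate
#' (lowest essential-feature RMSD; ties broken by more matched optional
#' features, then lexicographically smaller mapping).
#'
#' @param x A [molecule()] with conformers, or a `ph4_features` tibble
#'   (fixture path that bypasses chemistry).
#' @param model A [ph4_model()].
#' @param pair_tol Distance prefilter tolerance (Angstrom).
#' @param rmsd_cutoff Fitness acceptance cutoff (Angstrom).
#' @param max_confs Cap on conformers examined.
#' @param rules Perception rules when `x` is a molecule.
#' @return One-row tibble: `molecule_id`, `conformer`, `matched`,
#'   `rmsd`, `n_optional`, `reason`, and list-columns `mapping` and
#'   `transform`.
#' @export
match_pharmacophore <- function(x, model, pair_tol = 1.0, rmsd_cutoff = 1.2,
                                max_confs = Inf, rules = NULL) {
  stopifnot(is_ph4_model(model))
  if (inherits(x, "ph4_features")) {
    sets <- list(x)
  } else if (is_molecule(x)) {
    if (!length(x$conformers)) abort(sprintf("molecule '%s' has no conformer", x$id))
    idx <- seq_len(min(length(x$conformers), max_confs))
    rules <- rules %||% read_feature_rules()
    sets <- lapply(idx, function(k) perceive_features(x, k, rules))
  } else {
    abort("x must be a ps_mol or a ph4_features object")
  }
  mol_id <- if (inherits(x, "ph4_features")) attr(x, "molecule_id") else x$id

  best <- NULL
  best_diag <- list(rmsd = NA_real_, reason = "no correspondence",
                    conformer = NA_character_)
  for (fs in sets) {
    cands <- enumerate_correspondences(fs, model, pair_tol)
    if (!length(cands)) next
    for (cand in cands) {
      fit <- tryCatch(align_and_score(fs, cand, model), error = function(e) NULL)
      if (is.null(fit)) next
      if (!is.finite(best_diag$rmsd) || fit$rmsd < best_diag$rmsd) {
        best_diag <- list(rmsd = fit$rmsd, reason = "rmsd above cutoff",
                          conformer = attr(fs, "conformer"))
      }
      if (fit$rmsd > rmsd_cutoff) next
      ex <- check_exclusions(feature_coords(fs), fit$transform, model)
      if (!ex$pass) {
        if (best_diag$reason != "candidate found") {
          best_diag$reason <- "exclusion clash"
        }
        next
      }
      cand_rec <- list(rmsd = fit$rmsd, n_optional = length(cand$optional),
                       mapping = cand, transform = fit$transform,
                       conformer = attr(fs, "conformer"))
      if (is.null(best) || better_candidate(cand_rec, best)) best <- cand_rec
    }
  }

  if (is.null(best)) {
    return(tibble::tibble(
      molecule_id = mol_id, conformer = best_diag$conformer,
      matched = FALSE, rmsd = best_diag$rmsd, n_optional = NA_integer_,
      reason = best_diag$reason, mapping = list(NULL), transform = list(NULL)))
  }
  tibble::tibble(
    molecule_id = mol_id, conformer = best$conformer, matched = TRUE,
    rmsd = best$rmsd, n_optional = best$n_optional, reason = "matched",
    mapping = list(best$mapping), transform = list(best$transform))
}

# Ordering: lower rmsd, then more optional features, then lexicographic
# essential mapping.
better_candidate <- function(a, b) {
  if (a$rmsd != b$rmsd) return(a$rmsd < b$rmsd)
  if (a$n_optional != b$n_optional) return(a$n_optional > b$n_optional)
  av <- unname(a$mapping$essential); bv <- unname(b$mapping$essential)
  for (k in seq_along(av)) {
    if (av[k] != bv[k]) return(av[k] < bv[k])
  }
  FALSE
}
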