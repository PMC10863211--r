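# Conformer generation: seeded distance-geometry embedding (ETKDG via
# the RDKit toolkit, driven through the system Python). Deterministic
# for a fixed seed on one platform.

#' Generate conformers for a molecule
#'
#' Embeds up to `n` distinct 3D conformers with the ETKDG
#' distance-geometry method at a fixed random seed; explicit hydrogens
#' are added during embedding and kept on the returned molecule.
#' Conformers closer than `rmsd_min` to an earlier one are pruned as
#' duplicates, so rigid molecules yield a single conformer.
#'
#' @param mol A [molecule()].
#' @param n Maximum number of conformers.
#' @param seed Integer seed; a fixed seed gives bitwise-identical
#'   coordinates on one platform.
#' @param rmsd_min Duplicate-pruning threshold in Angstrom.
#' @param minimize Force-field (MMFF) relaxation of each conformer;
#'   off by default.
#' @return The molecule with its atom table (now including explicit
#'   hydrogens) and `conformers` list replaced. If embedding fails the
#'   input molecule is returned unchanged with attribute
#'   `embed_failed = TRUE` and a warning, so callers can exclude it
#'   downstream.
#' @export
generate_conformers <- function(mol, n = 10, seed = 1, rmsd_min = 0.1,
                                minimize = FALSE) {
  stopifnot(is_molecule(mol), n >= 1)
  py <- Sys.which(c("python", "python3"))
  py <- py[nzchar(py)][1]
  if (is.na(py)) abort("no python interpreter found for conformer embedding")
  script <- system.file("scripts", "embed_conformers.py",
                        package = "pharmscreen")
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_sdf(mol, tmp_in)
  status <- suppressWarnings(system2(py, c(
    shQuote(script), shQuote(tmp_in), shQuote(tmp_out),
    as.integer(n), as.integer(seed), format(rmsd_min),
    if (minimize) "1" else "0"), stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(tmp_out)) {
    warn(sprintf("molecule '%s': 3D embedding failed; flagged for exclusion",
                 mol$id))
    attr(mol, "embed_failed") <- TRUE
    return(mol)
  }
  recs <- suppressWarnings(read_sdf(tmp_out))
  if (!length(recs)) {
    warn(sprintf("molecule '%s': 3D embedding produced no conformers", mol$id))
    attr(mol, "embed_failed") <- TRUE
    return(mol)
  }
  out <- recs[[1]]
  out$id <- mol$id
  out$properties <- mol$properties
  out$smiles <- mol$smiles
  confs <- lapply(recs, function(r) r$conformers[[1]])
  names(confs) <- paste0("conf", seq_along(confs))
  out$conformers <- confs
  out
}

#' Count conformers across a library
#'
#' Convenience wrapper running [generate_conformers()] over a library
#' and reporting per-molecule conformer counts (embedding failures
#' count zero and are flagged).
#'
#' @param mols List of [molecule()]s.
#' @param n,seed,rmsd_min,minimize Passed to [generate_conformers()].
#' @return List with `molecules` (embedded library) and `counts`
#'   (tibble: `id`, `n_conformers`, `embed_failed`).
#' @export
embed_library <- function(mols, n = 10, seed = 1, rmsd_min = 0.1,
                          minimize = FALSE) {
  out <- lapply(seq_along(mols), function(k)
    generate_conformers(mols[[k]], n = n, seed = seed + k - 1L,
                        rmsd_min = rmsd_min, minimize = minimize))
  counts <- tibble::tibble(
    id = vapply(mols, function(m) m$id, character(1)),
    n_conformers = vapply(out, function(m)
      if (isTRUE(attr(m, "embed_failed"))) 0L else length(m$conformers),
      integer(1)),
    embed_failed = vapply(out, function(m)
      isTRUE(attr(m, "embed_failed")), logical(1)))
  list(molecules = out, counts = counts)
}
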