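# Descriptor computation and the post-screening hit-filtration cascade:
# deduplication, screening window, Lipinski, Veber, toxicophore alerts,
# polarity and solubility cutoffs, Oprea lead-likeness and PAINS.

#' Compute the descriptor set used by the filtration cascade
#'
#' Molecular weight, atomic-contribution logP (reported as both `clogp`
#' and `wlogp`; OpenBabel exposes a single Wildman-Crippen-type
#' estimator), Ertl topological polar surface area, hydrogen-bond
#' donors (N-H/O-H) and acceptors (N+O count), rotatable bonds (single,
#' acyclic, non-terminal, amide C-N excluded), ring count (cyclomatic),
#' aromatic heavy-atom fraction and an ESOL log10 aqueous solubility
#' estimate.
#'
#' @param mols A `ps_mol`, list of them, or character vector of SMILES.
#' @return Tibble with one row per molecule: `id`, `key` (canonical
#'   SMILES), `mw`, `clogp`, `wlogp`, `tpsa`, `hbd`, `hba`, `rotb`,
#'   `rings`, `aromatic_fraction`, `logs`. Molecules whose descriptor
#'   calculation fails are dropped with a warning (and listed in the
#'   `failed` attribute).
#' @export
compute_descriptors <- function(mols) {
  if (is.character(mols)) mols <- parse_smiles(mols)
  if (is_molecule(mols)) mols <- list(mols)
  if (!length(mols)) {
    return(tibble::tibble(id = character(), key = character(), mw = numeric(),
                          clogp = numeric(), wlogp = numeric(), tpsa = numeric(),
                          hbd = integer(), hba = integer(), rotb = integer(),
                          rings = integer(), aromatic_fraction = numeric(),
                          logs = numeric()))
  }
  props <- ob_props(mols)
  keys <- canonical_key(mols)
  rotb <- count_rotatable(mols)
  rows <- vector("list", length(mols))
  failed <- character(0)
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    row <- tryCatch({
      el <- m$atoms$element
      heavy <- el != "H"
      nH <- hydrogen_count(m)
      arom <- aromatic_atoms(m)
      nring <- nrow(m$bonds) - nrow(m$atoms) +
        length(unique(fragment_ids(m)))
      af <- if (sum(heavy)) sum(arom & heavy) / sum(heavy) else 0
      lp <- as.numeric(props$logP[k])
      mw <- as.numeric(props$MW[k])
      rb <- rotb[k]
      tibble::tibble(
        id = m$id, key = keys[k],
        mw = mw, clogp = lp, wlogp = lp,
        tpsa = as.numeric(props$TPSA[k]),
        hbd = sum(el %in% c("N", "O") & nH >= 1),
        hba = sum(el %in% c("N", "O")),
        rotb = rb,
        rings = as.integer(max(0, nring)),
        aromatic_fraction = af,
        logs = esol_logs(lp, mw, rb, af))
    }, error = function(e) NULL)
    if (is.null(row)) failed <- c(failed, m$id) else rows[[k]] <- row
  }
  if (length(failed)) {
    warn(sprintf("descriptor calculation failed for: %s",
                 paste(failed, collapse = ", ")))
  }
  structure(dplyr::bind_rows(rows), failed = failed)
}

# Rotatable bonds via SMARTS: generic non-terminal acyclic single bonds
# minus acyclic amide C-N bonds.
count_rotatable <- function(mols) {
  generic <- ob_smarts_count(mols, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]")
  amide <- ob_smarts_count(mols, "[CX3](=[OX1])-&!@[NX3!D1]")
  as.integer(pmax(0, generic - amide))
}

# ESOL linear solubility model (coefficients shipped as a data file).
esol_logs <- function(clogp, mw, rotb, aromatic_fraction) {
  co <- esol_coefficients()
  unname(co["intercept"] + co["clogp"] * clogp + co["mw"] * mw +
           co["rotb"] * rotb + co["aromatic_fraction"] * aromatic_fraction)
}

esol_coefficients <- function() {
  path <- system.file("extdata", "esol_coefficients.tsv", package = "pharmscreen")
  raw <- utils::read.delim(path, comment.char = "#")
  setNames(raw$value, raw$term)
}

#' Count Lipinski rule-of-five violations
#'
#' Violations counted: `mw >= 500`, `clogp > 5`, `hbd > 5`, `hba > 10`
#' (the weight bound is "< 500", so exactly 500 Da violates).
#'
#' @param d Descriptor tibble from [compute_descriptors()].
#' @return Integer vector (0-4), one per row.
#' @export
lipinski_violations <- function(d) {
  as.integer((d$mw >= 500) + (d$clogp > 5) + (d$hbd > 5) + (d$hba > 10))
}

#' Single-rule filter predicates
#'
#' `veber_pass`: rotatable bonds <= 10 and TPSA < 140 A^2.
#' `screening_window_pass`: 350 <= MW <= 500 Da and rotatable bonds
#' <= 10 (the virtual-screening window).
#' `logs_pass`: ESOL logS >= -5 (compounds less soluble are removed).
#'
#' @param d Descriptor tibble from [compute_descriptors()].
#' @return Logical vector, one per row.
#' @export
veber_pass <- function(d) d$rotb <= 10 & d$tpsa < 140

#' @rdname veber_pass
#' @export
screening_window_pass <- function(d) d$mw >= 350 & d$mw <= 500 & d$rotb <= 10

#' @rdname veber_pass
#' @export
logs_pass <- function(d) d$logs >= -5

#' Oprea lead-likeness filter
#'
#' Conjunction of an editable ruleset; the shipped default bounds are
#' `mw <= 450`, `-3.5 <= clogp <= 4.5`, `rings <= 4`, `rotb <= 10`,
#' `hbd <= 5`, `hba <= 8` (several variants of the lead-like criteria
#' circulate; the bounds are configuration, not code).
#'
#' @param d Descriptor tibble.
#' @param ruleset Named list of bounds; any of `mw_max`, `clogp_min`,
#'   `clogp_max`, `rings_max`, `rotb_max`, `hbd_max`, `hba_max`.
#' @return Logical vector.
#' @export
oprea_leadlike_pass <- function(d, ruleset = default_leadlike_rules()) {
  known <- c("mw_max", "clogp_min", "clogp_max", "rings_max", "rotb_max",
             "hbd_max", "hba_max")
  bad <- setdiff(names(ruleset), known)
  if (length(bad)) abort(sprintf("unknown lead-like rule key: %s", bad[1]))
  ok <- rep(TRUE, nrow(d))
  g <- function(key) ruleset[[key]]
  if (!is.null(g("mw_max"))) ok <- ok & d$mw <= g("mw_max")
  if (!is.null(g("clogp_min"))) ok <- ok & d$clogp >= g("clogp_min")
  if (!is.null(g("clogp_max"))) ok <- ok & d$clogp <= g("clogp_max")
  if (!is.null(g("rings_max"))) ok <- ok & d$rings <= g("rings_max")
  if (!is.null(g("rotb_max"))) ok <- ok & d$rotb <= g("rotb_max")
  if (!is.null(g("hbd_max"))) ok <- ok & d$hbd <= g("hbd_max")
  if (!is.null(g("hba_max"))) ok <- ok & d$hba <= g("hba_max")
  ok
}

#' @rdname oprea_leadlike_pass
#' @export
default_leadlike_rules <- function() {
  list(mw_max = 450, clogp_min = -3.5, clogp_max = 4.5,
       rings_max = 4, rotb_max = 10, hbd_max = 5, hba_max = 8)
}

#' Substructure alerts (PAINS / toxicophores)
#'
#' Matches molecules against an editable SMARTS alert file. The shipped
#' sets are curated, documented subsets of the published PAINS families
#' (frequent-hitter substructures) and of published mutagenicity
#' toxicophores (aromatic nitro, aromatic amine, epoxide, ...).
#'
#' @param mols `ps_mol` list or SMILES character vector.
#' @param alert_set `"pains"` or `"mutagenic"`, or a path to a custom
#'   alert file (TSV: columns `name`, `smarts`).
#' @return List (one element per molecule) of matched alert names;
#'   empty character vector = clean.
#' @export
substructure_alerts <- function(mols, alert_set = c("pains", "mutagenic")) {
  if (is.character(mols) && length(mols) && !file.exists(mols[1])) {
    mols <- parse_smiles(mols)
  }
  if (is_molecule(mols)) mols <- list(mols)
  path <- if (alert_set[1] %in% c("pains", "mutagenic")) {
    system.file("extdata", paste0(alert_set[1], "_alerts.tsv"),
                package = "pharmscreen")
  } else alert_set[1]
  alerts <- utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(alerts))) {
    abort(sprintf("alert file %s needs columns name, smarts", path))
  }
  if (!length(mols)) return(list())
  hit_mat <- matrix(0L, nrow = length(mols), ncol = nrow(alerts))
  for (a in seq_len(nrow(alerts))) {
    counts <- tryCatch(
      ob_smarts_count(mols, alerts$smarts[a]),
      error = function(e) abort(sprintf(
        "malformed SMARTS in %s line %d ('%s')", path, a, alerts$name[a])))
    hit_mat[, a] <- as.integer(counts > 0)
  }
  lapply(seq_along(mols), function(k) alerts$name[hit_mat[k, ] > 0])
}

#' Default cascade configuration
#'
#' One block per stage in cascade order: `dedup`, `window`, `lipinski`,
#' `veber`, `mutagenic`, `tpsa`, `logs`, `oprea`, `pains`; each with
#' `enabled` and its cutoffs. Serializable to YAML with
#' [write_cascade_config()].
#'
#' @return Named list of stage configurations.
#' @export
default_cascade_config <- function() {
  list(
    dedup = list(enabled = TRUE),
    window = list(enabled = TRUE, mw_min = 350, mw_max = 500, rotb_max = 10),
    lipinski = list(enabled = TRUE, max_violations = 1),
    veber = list(enabled = TRUE, rotb_max = 10, tpsa_max = 140),
    mutagenic = list(enabled = TRUE),
    tpsa = list(enabled = TRUE, tpsa_max = 140),
    logs = list(enabled = TRUE, logs_min = -5),
    oprea = list(enabled = TRUE),
    pains = list(enabled = TRUE))
}

#' @rdname default_cascade_config
#' @param config Cascade configuration list.
#' @param path YAML path.
#' @export
write_cascade_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_cascade_config
#' @export
read_cascade_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_cascade_config()
  for (nm in names(cfg)) base[[nm]] <- utils::modifyList(base[[nm]] %||% list(), cfg[[nm]])
  base
}

#' Apply the hit-filtration cascade
#'
#' Runs the full post-screening cascade over a descriptor library:
#' deduplicate by canonical key, screening window, at most one Lipinski
#' violation, Veber, toxicophore-clean, TPSA, logS, Oprea lead-likeness,
#' PAINS-clean. Every filter is a pure predicate of the descriptor row
#' (plus alert counts), so the surviving set is independent of stage
#' order; the per-stage counts of course depend on it.
#'
#' @param library Either a list of [molecule()]s / SMILES vector (alert
#'   stages computed from structure), or a descriptor tibble from
#'   [compute_descriptors()] or [gen_property_library()]; descriptor
#'   tibbles may carry precomputed `pains_n` / `mutagenic_n` alert
#'   counts (fixture path).
#' @param config Stage configuration, see [default_cascade_config()].
#' @return A `ph4_filter_report`: list with `report` (per-molecule rule
#'   booleans and overall `pass`) and `stages` (per-stage in/removed/out
#'   counts, monotonically non-increasing).
#' @export
apply_cascade <- function(library, config = default_cascade_config()) {
  if (is.data.frame(library)) {
    d <- tibble::as_tibble(library)
  } else {
    d <- compute_descriptors(library)
    al_p <- substructure_alerts(library, "pains")
    al_m <- substructure_alerts(library, "mutagenic")
    d$pains_n <- vapply(al_p, length, integer(1))
    d$mutagenic_n <- vapply(al_m, length, integer(1))
  }
  if (!"key" %in% names(d)) d$key <- d$id
  if (!"pains_n" %in% names(d)) d$pains_n <- 0L
  if (!"mutagenic_n" %in% names(d)) d$mutagenic_n <- 0L

  cfg <- config
  on_stage <- function(nm) isTRUE(cfg[[nm]]$enabled)
  rep_tbl <- tibble::tibble(id = d$id, key = d$key)
  rep_tbl$dedup <- !duplicated(d$key) | !on_stage("dedup")
  rep_tbl$window <- if (on_stage("window"))
    d$mw >= cfg$window$mw_min & d$mw <= cfg$window$mw_max &
      d$rotb <= cfg$window$rotb_max else TRUE
  rep_tbl$lipinski <- if (on_stage("lipinski"))
    lipinski_violations(d) <= cfg$lipinski$max_violations else TRUE
  rep_tbl$veber <- if (on_stage("veber"))
    d$rotb <= cfg$veber$rotb_max & d$tpsa < cfg$veber$tpsa_max else TRUE
  rep_tbl$mutagenic <- if (on_stage("mutagenic")) d$mutagenic_n == 0 else TRUE
  rep_tbl$tpsa <- if (on_stage("tpsa")) d$tpsa < cfg$tpsa$tpsa_max else TRUE
  rep_tbl$logs <- if (on_stage("logs")) d$logs >= cfg$logs$logs_min else TRUE
  rep_tbl$oprea <- if (on_stage("oprea")) oprea_leadlike_pass(d) else TRUE
  rep_tbl$pains <- if (on_stage("pains")) d$pains_n == 0 else TRUE

  stage_names <- c("dedup", "window", "lipinski", "veber", "mutagenic",
                   "tpsa", "logs", "oprea", "pains")
  rep_tbl$pass <- Reduce(`&`, rep_tbl[stage_names])
  alive <- rep(TRUE, nrow(rep_tbl))
  stages <- list()
  for (s in stage_names) {
    n_in <- sum(alive)
    alive <- alive & rep_tbl[[s]]
    stages[[length(stages) + 1]] <- tibble::tibble(
      stage = s, enabled = on_stage(s), n_in = n_in,
      n_removed = n_in - sum(alive), n_out = sum(alive))
  }
  structure(list(report = rep_tbl, stages = dplyr::bind_rows(stages),
                 config = cfg),
            class = "ph4_filter_report")
}

#' @export
print.ph4_filter_report <- function(x, ...) {
  cat(sprintf("<ph4_filter_report> %d molecules in, %d pass\n",
              nrow(x$report), sum(x$report$pass)))
  print(x$stages)
  invisible(x)
}

#' Survivors of a filter report
#'
#' @param report A `ph4_filter_report`.
#' @return Tibble with `id` and `key` of passing molecules.
#' @export
cascade_survivors <- function(report) {
  report$report[report$report$pass, c("id", "key")]
}

#' Intersect two hit sets by canonical key
#'
#' @param set_a,set_b Tibbles with `id` and `key` columns (e.g. from
#'   [cascade_survivors()]), or character vectors of keys.
#' @return Tibble of common compounds (key plus ids from both sets),
#'   ordered by key.
#' @export
intersect_hits <- function(set_a, set_b) {
  norm <- function(s, side) {
    if (is.character(s)) tibble::tibble(id = s, key = s) else
      tibble::as_tibble(s)[, c("id", "key")]
  }
  a <- norm(set_a); b <- norm(set_b)
  a <- a[!duplicated(a$key), ]
  b <- b[!duplicated(b$key), ]
  common <- dplyr::inner_join(a, b, by = "key", suffix = c("_a", "_b"))
  common <- common[order(common$key), c("key", "id_a", "id_b")]
  tibble::as_tibble(common)
}
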