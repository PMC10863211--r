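# Screening drivers and the enrichment metric battery.  All metrics are
# ratios of small integers, so they are computed and compared as exact
# rationals; rendering to two decimals (round half away from zero, or a
# strict truncation mode) happens only at output time.

#' Screen a library against one or more pharmacophore models
#'
#' @param models A [ph4_model()] or list of them.
#' @param library List of [molecule()]s and/or `ph4_features` fixtures.
#' @param pair_tol,rmsd_cutoff,max_confs Matcher parameters, see
#'   [match_pharmacophore()].
#' @return A `ph4_screen` tibble: one row per model x molecule with the
#'   match diagnostics; hits are the rows with `matched == TRUE`.
#' @export
screen_library <- function(models, library, pair_tol = 1.0,
                           rmsd_cutoff = 1.2, max_confs = Inf) {
  if (is_ph4_model(models)) models <- list(models)
  if (!length(models)) abort("empty model list")
  empty <- tibble::tibble(
    molecule_id = character(), conformer = character(), matched = logical(),
    rmsd = numeric(), n_optional = integer(), reason = character(),
    mapping = list(), transform = list())
  rows <- lapply(models, function(m) {
    res <- dplyr::bind_rows(c(list(empty), lapply(library, function(x)
      match_pharmacophore(x, m, pair_tol = pair_tol,
                          rmsd_cutoff = rmsd_cutoff, max_confs = max_confs))))
    res$model <- rep(m$name, nrow(res))
    res
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("model", setdiff(names(out), "model"))]
  class(out) <- c("ph4_screen", class(out))
  out
}

#' Hit identifiers of a screen result
#'
#' @param screen A `ph4_screen` tibble from [screen_library()].
#' @param model Optional model name filter.
#' @return Character vector of matched molecule ids.
#' @export
screen_hits <- function(screen, model = NULL) {
  if (!is.null(model)) screen <- screen[screen$model == model, ]
  screen$molecule_id[screen$matched]
}

#' Build a confusion matrix from hits and activity labels
#'
#' @param hits Character vector of hit molecule ids.
#' @param labels Activity records: tibble with `id` and `label`
#'   (`active`, `inactive` or `decoy`; everything not `active` counts as
#'   inactive for the confusion matrix), optionally `ic50` in nM.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_hits <- function(hits, labels) {
  labels <- check_activity_records(labels)
  unknown <- setdiff(hits, labels$id)
  if (length(unknown)) {
    abort(sprintf("hits without activity label: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  act <- labels$id[labels$label == "active"]
  dec <- labels$id[labels$label != "active"]
  tibble::tibble(
    tp = length(intersect(hits, act)),
    fp = length(intersect(hits, dec)),
    tn = length(setdiff(dec, hits)),
    fn = length(setdiff(act, hits)))
}

#' Validate (and complete) activity records
#'
#' Enforces the activity-record contract: when an IC50 is present the
#' label must agree with the 10 uM cutoff (`active` strictly below,
#' `inactive` at or above), and decoys carry no IC50. Missing labels are
#' derived from the IC50.
#'
#' @param labels Tibble with `id`, optional `ic50` (nM), optional
#'   `label`.
#' @param cutoff_nm Activity cutoff in nM (default 10000 = 10 uM).
#' @return The validated tibble with a complete `label` column.
#' @export
check_activity_records <- function(labels, cutoff_nm = 10000) {
  labels <- tibble::as_tibble(labels)
  if (!"id" %in% names(labels)) abort("activity records need an 'id' column")
  if (anyDuplicated(labels$id)) abort("duplicate molecule ids in activity records")
  if (!"ic50" %in% names(labels)) labels$ic50 <- NA_real_
  if (!"label" %in% names(labels)) labels$label <- NA_character_
  derived <- ifelse(labels$ic50 < cutoff_nm, "active", "inactive")
  labels$label <- ifelse(is.na(labels$label), derived, labels$label)
  bad <- !is.na(labels$ic50) & !is.na(labels$label) & labels$label != derived
  if (any(bad)) {
    abort(sprintf("label of '%s' contradicts its IC50 under the %.0f nM cutoff",
                  labels$id[bad][1], cutoff_nm))
  }
  if (any(labels$label == "decoy" & !is.na(labels$ic50))) {
    abort("decoys must not carry an IC50")
  }
  if (any(is.na(labels$label))) abort("records with neither label nor IC50")
  labels
}

# ---- exact rational helpers -------------------------------------------------

# Render num/den at `digits` decimals, rounding half away from zero.
# Integer arithmetic throughout, so 0.475 -> "0.48" reliably.
round_rational <- function(num, den, digits = 2) {
  stopifnot(all(den > 0))
  s <- 10^digits
  q <- (2 * s * num + den) %/% (2 * den)  # floor(s*num/den + 1/2)
  sprintf(paste0("%.", digits, "f"), q / s)
}

# Truncation rendering (digits chopped, never rounded up).
trunc_rational <- function(num, den, digits = 2) {
  s <- 10^digits
  sprintf(paste0("%.", digits, "f"), ((s * num) %/% den) / s)
}

# Compare two non-negative rationals by cross multiplication.
# Returns -1, 0, 1.
cmp_rational <- function(n1, d1, n2, d2) {
  sign(n1 * d2 - n2 * d1)
}

#' Compute the enrichment metric battery from a confusion matrix
#'
#' Given TP/FP/TN/FN, computes sensitivity `se = TP/(TP+FN)`,
#' specificity `sp = TN/(TN+FP)`, yield of actives `ya = TP/(TP+FP)`,
#' enrichment `e = ya / (A/N)` with `A` the actives and `N` the library
#' size, accuracy `acc = (TP+TN)/N`, discrimination ratio `dr = se/sp`,
#' and `f1 = 2 TP / (2 TP + FP + FN)`. All values are exact ratios of
#' the input integers; use [format_metrics()] to render them at two
#' decimals the way assessment tables print them.
#'
#' Some published assessment tables compute Ya and E with the screening
#' tool's reported hit count `n = TP+FP+FN` (hits plus missed actives)
#' as denominator rather than `TP+FP`; set
#' `ya_denominator = "hits_plus_misses"` to reproduce those columns.
#'
#' @param counts One-row tibble (or list) with `tp`, `fp`, `tn`, `fn`.
#' @param model Optional model name carried into the row.
#' @param ya_denominator `"hits"` (default, `TP+FP`) or
#'   `"hits_plus_misses"` (`TP+FP+FN`).
#' @return A `ph4_metrics` tibble row: counts, `n` (hit count under the
#'   chosen convention), the seven metrics as numerics, and `flags`
#'   (e.g. `"no_hits"`, `"sp_zero"`).
#' @export
compute_metrics <- function(counts, model = NA_character_,
                            ya_denominator = c("hits", "hits_plus_misses")) {
  ya_denominator <- match.arg(ya_denominator)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) abort("negative confusion counts")
  a <- tp + fn          # actives
  d <- fp + tn          # decoys/inactives
  n_total <- a + d
  if (n_total == 0) abort("empty confusion matrix")
  nden <- if (ya_denominator == "hits") tp + fp else tp + fp + fn
  flags <- character(0)
  if (tp + fp == 0) flags <- c(flags, "no_hits")
  if (tn == 0 && d > 0) flags <- c(flags, "sp_zero")
  frac <- function(num, den) if (den > 0) num / den else NA_real_

  tibble::tibble(
    model = model,
    n = tp + fp, n_reported = nden,
    tp = tp, fp = fp, tn = tn, fn = fn,
    se = frac(tp, a),
    sp = frac(tn, d),
    ya = if (nden > 0) tp / nden else 0,
    e = if (a > 0 && nden > 0) (tp * n_total) / (nden * a) else 0,
    acc = (tp + tn) / n_total,
    dr = if (tn > 0) (tp * d) / (a * tn) else NA_real_,
    f1 = frac(2 * tp, 2 * tp + fp + fn),
    ya_denominator = ya_denominator,
    flags = paste(flags, collapse = ","))
}

#' Render a metric table at fixed precision
#'
#' @param rows Tibble of [compute_metrics()] rows.
#' @param digits Decimal places (default 2, the usual table rendering).
#' @param mode `"round"` (half away from zero) or `"truncate"`.
#' @return Tibble with the metric columns as character, counts retained.
#' @export
format_metrics <- function(rows, digits = 2, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  rend <- if (mode == "round") round_rational else trunc_rational
  out <- rows
  for (k in seq_len(nrow(rows))) {
    tp <- rows$tp[k]; fp <- rows$fp[k]; tn <- rows$tn[k]; fn <- rows$fn[k]
    a <- tp + fn; d <- fp + tn; n_total <- a + d
    nden <- rows$n_reported[k]
    cell <- function(num, den) {
      if (den > 0) rend(num, den, digits) else "NA"
    }
    out$se[k] <- cell(tp, a)
    out$sp[k] <- cell(tn, d)
    out$ya[k] <- if (nden > 0) cell(tp, nden) else "0.00"
    out$e[k] <- if (a > 0 && nden > 0) cell(tp * n_total, nden * a) else "0.00"
    out$acc[k] <- cell(tp + tn, n_total)
    out$dr[k] <- if (tn > 0) cell(tp * d, a * tn) else "NA"
    out$f1[k] <- cell(2 * tp, 2 * tp + fp + fn)
  }
  out
}

#' Rank pharmacophore models by a metric
#'
#' Orders metric rows descending by the chosen key using exact rational
#' comparison of the underlying counts (so 76/154 ranks above 78/162
#' even though both print as 0.49/0.48), and annotates each model with a
#' bias flag: models with specificity below `bias_cutoff` are "biased
#' toward actives" (they accept almost everything), models with
#' sensitivity below it are "biased toward decoys".
#'
#' @param rows Tibble of [compute_metrics()] rows.
#' @param key One of `"f1"` (default), `"se"`, `"sp"`, `"ya"`, `"acc"`.
#' @param bias_cutoff Threshold for the bias flags (default 0.5).
#' @return The rows ordered by the key, with columns `rank` and `bias`.
#' @export
rank_models <- function(rows, key = "f1", bias_cutoff = 0.5) {
  if (!nrow(rows)) abort("no metric rows to rank")
  key <- match.arg(key, c("f1", "se", "sp", "ya", "acc"))
  numden <- lapply(seq_len(nrow(rows)), function(k) {
    tp <- rows$tp[k]; fp <- rows$fp[k]; tn <- rows$tn[k]; fn <- rows$fn[k]
    switch(key,
      f1 = c(2 * tp, max(1, 2 * tp + fp + fn)),
      se = c(tp, max(1, tp + fn)),
      sp = c(tn, max(1, tn + fp)),
      ya = c(tp, max(1, rows$n_reported[k])),
      acc = c(tp + tn, tp + fp + tn + fn))
  })
  ord <- order(vapply(numden, function(x) x[1] / x[2], numeric(1)),
               decreasing = TRUE)
  # refine equal-double neighbours with exact comparison (stable)
  exact_lt <- function(i, j) {
    cmp_rational(numden[[i]][1], numden[[i]][2],
                 numden[[j]][1], numden[[j]][2]) < 0
  }
  for (pass in seq_len(nrow(rows))) {
    swapped <- FALSE
    for (k in seq_len(length(ord) - 1)) {
      if (exact_lt(ord[k], ord[k + 1])) {
        tmp <- ord[k]; ord[k] <- ord[k + 1]; ord[k + 1] <- tmp
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  out <- rows[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$bias <- dplyr::case_when(
    out$sp < bias_cutoff ~ "biased toward actives",
    out$se < bias_cutoff ~ "biased toward decoys",
    TRUE ~ "balanced")
  out
}

#' Write an assessment table as TSV
#'
#' Columns `Ph4-no, N, TP, FP, TN, FN, Se, Sp, Ya, E, Acc, Dr, F1` with
#' two-decimal rendering; missing metrics are rendered `NA`.
#'
#' @param rows Tibble of [compute_metrics()] rows.
#' @param path Output path.
#' @param mode Rendering mode, see [format_metrics()].
#' @return `path`, invisibly.
#' @export
write_assessment_table <- function(rows, path, mode = "round") {
  if (!nrow(rows)) abort("no rows to write")
  fmt <- format_metrics(rows, mode = mode)
  out <- tibble::tibble(
    `Ph4-no` = fmt$model, N = fmt$n_reported,
    TP = fmt$tp, FP = fmt$fp, TN = fmt$tn, FN = fmt$fn,
    Se = fmt$se, Sp = fmt$sp, Ya = fmt$ya, E = fmt$e,
    Acc = fmt$acc, Dr = fmt$dr, F1 = fmt$f1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assessment table written by [write_assessment_table()]
#'
#' @param path TSV path.
#' @return Tibble with the table columns (metrics as character cells).
#' @export
read_assessment_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      colClasses = "character"))
}

#' Published kinase assessment tables shipped with the package
#'
#' Confusion counts and printed metric cells of the two published
#' pharmacophore assessment tables (20 VEGFR2 models screened against
#' 40 actives/1200 decoys; 14 FAK models against 17 actives/983
#' decoys), as transcribed from the publication. Note two documented
#' quirks of the VEGFR2 table: its `N` column equals `TP+FP+FN` (hits
#' plus missed actives) and its printed Ya/E cells use that `N` as
#' denominator, whereas the FAK table uses the standard `TP+FP`.
#'
#' @param target `"vegfr2"` or `"fak"`.
#' @return Tibble with columns `model`, `n`, `tp`, `fp`, `tn`, `fn` and
#'   the printed cells `se`, `sp`, `ya`, `e`, `acc`, `dr`, `f1` as
#'   character strings.
#' @export
assessment_counts <- function(target = c("vegfr2", "fak")) {
  target <- match.arg(target)
  fn <- c(vegfr2 = "vegfr2_assessment_table.tsv",
          fak = "fak_assessment_table.tsv")[[target]]
  raw <- utils::read.delim(system.file("extdata", fn, package = "pharmscreen"),
                           colClasses = "character", comment.char = "#")
  tibble::tibble(
    model = raw$model, n = as.integer(raw$n),
    tp = as.integer(raw$tp), fp = as.integer(raw$fp),
    tn = as.integer(raw$tn), fn = as.integer(raw$fn),
    se = raw$se, sp = raw$sp, ya = raw$ya, e = raw$e,
    acc = raw$acc, dr = raw$dr, f1 = raw$f1)
}
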