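# Confusion-matrix bookkeeping and the enrichment metric battery,
# anchored on the published kinase assessment tables.

test_that("evaluate_hits builds the confusion matrix and validates ids", {
  labels <- tibble::tibble(id = c("a1", "a2", "d1", "d2", "d3"),
                           label = c("active", "active", "decoy", "decoy",
                                     "decoy"))
  cc <- evaluate_hits(c("a1", "a2"), labels)
  expect_equal(unlist(cc), c(tp = 2, fp = 0, tn = 3, fn = 0))
  expect_error(evaluate_hits(c("a1", "zz"), labels), "zz")
  # label permutation property: tp + fn is always the number of actives
  set.seed(3)
  for (rep in 1:20) {
    labs <- tibble::tibble(id = sprintf("m%02d", 1:20),
                           label = sample(c("active", "decoy"), 20,
                                          replace = TRUE))
    hits <- sample(labs$id, sample(0:20, 1))
    cc <- evaluate_hits(hits, labs)
    expect_equal(cc$tp + cc$fn, sum(labs$label == "active"))
    expect_equal(cc$fp + cc$tn, sum(labs$label != "active"))
  }
})

test_that("activity records derive labels from the 10 uM cutoff", {
  recs <- check_activity_records(tibble::tibble(
    id = c("a", "b", "c"), ic50 = c(500, 25000, NA), label = c(NA, NA, "decoy")))
  expect_equal(recs$label, c("active", "inactive", "decoy"))
  expect_error(check_activity_records(tibble::tibble(
    id = "x", ic50 = 500, label = "inactive")), "contradicts")
  expect_error(check_activity_records(tibble::tibble(
    id = "d", ic50 = 100, label = "decoy")), "contradicts|IC50")
})

test_that("the metric battery reproduces the published FAK example row", {
  row <- compute_metrics(list(tp = 15, fp = 17, tn = 966, fn = 2),
                         model = "FAK_Ph4-12")
  fmt <- format_metrics(row)
  expect_equal(fmt$se, "0.88")
  expect_equal(fmt$sp, "0.98")
  expect_equal(fmt$ya, "0.47")
  expect_equal(fmt$e, "27.57")
  expect_equal(fmt$acc, "0.98")
  expect_equal(fmt$dr, "0.90")
  expect_equal(fmt$f1, "0.61")
})

test_that("perfect and degenerate classifiers hit the analytic corners", {
  perfect <- compute_metrics(list(tp = 40, fp = 0, tn = 1200, fn = 0))
  expect_equal(perfect$se, 1)
  expect_equal(perfect$sp, 1)
  expect_equal(perfect$ya, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$e, 1240 / 40)
  none <- compute_metrics(list(tp = 0, fp = 0, tn = 1200, fn = 40))
  expect_equal(none$ya, 0)
  expect_equal(none$e, 0)
  expect_match(none$flags, "no_hits")
})

test_that("metric identities hold exactly on random confusion matrices", {
  set.seed(11)
  for (rep in 1:50) {
    tp <- sample(0:40, 1); fn <- sample(0:40, 1)
    fp <- sample(0:500, 1); tn <- sample(1:1200, 1)
    if (tp + fn == 0) fn <- 1
    r <- compute_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
    n_total <- tp + fp + tn + fn
    a <- tp + fn
    if (tp + fp > 0) {
      expect_equal(r$e, r$ya * n_total / a, tolerance = 1e-12)
      # f1 is the harmonic mean of ya and se
      if (tp > 0) {
        expect_equal(r$f1, 2 / (1 / r$ya + 1 / r$se), tolerance = 1e-12)
      }
    }
    if (!is.na(r$dr)) expect_equal(r$dr * r$sp, r$se, tolerance = 1e-12)
    expect_gte(r$acc, min(r$se, r$sp) - 1e-12)
    expect_lte(r$acc, max(r$se, r$sp) + 1e-12)
  }
})

test_that("two-decimal rendering rounds half away from zero; truncation mode chops", {
  # 76/160 = 0.475 must render 0.48 under rounding
  r <- compute_metrics(list(tp = 38, fp = 82, tn = 1118, fn = 2))
  expect_equal(format_metrics(r)$f1, "0.48")
  expect_equal(format_metrics(r, mode = "truncate")$f1, "0.47")
  # 38/120 renders 0.32 rounded, 0.31 truncated
  expect_equal(format_metrics(r)$ya, "0.32")
  expect_equal(format_metrics(r, mode = "truncate")$ya, "0.31")
})

test_that("model ranking uses exact rational comparison with bias flags", {
  fak <- assessment_counts("fak")
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(fak)), function(k)
    compute_metrics(fak[k, c("tp", "fp", "tn", "fn")], model = fak$model[k])))
  ranked <- rank_models(rows)
  expect_equal(ranked$model[1:3], c("FAK_Ph4-9", "FAK_Ph4-10", "FAK_Ph4-12"))
  expect_equal(ranked$bias[ranked$model == "FAK_Ph4-2"], "biased toward actives")
  # exact rationals: 28/43 beats 30/49 even though both print 0.6x
  expect_lt(which(ranked$model == "FAK_Ph4-9"),
            which(ranked$model == "FAK_Ph4-12"))
  expect_error(rank_models(rows[0, ]), "no metric rows")
})

test_that("assessment tables render, write and re-read losslessly", {
  fak <- assessment_counts("fak")
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(fak)), function(k)
    compute_metrics(fak[k, c("tp", "fp", "tn", "fn")], model = fak$model[k])))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_assessment_table(rows, tmp)
  back <- read_assessment_table(tmp)
  expect_equal(nrow(back), 14)
  expect_equal(back$`Ph4-no`, fak$model)
  expect_equal(as.numeric(back$F1), as.numeric(fak$f1))
  expect_equal(as.numeric(back$Se), as.numeric(fak$se))
})

test_that("screening an empty library or empty model list behaves", {
  m <- load_kinase_model("fak")
  expect_error(screen_library(list(), list(feature_set("ACC", matrix(0, 1, 3)))),
               "empty model")
  res <- screen_library(m, list())
  expect_equal(nrow(res), 0)
  expect_length(screen_hits(res), 0)
})
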