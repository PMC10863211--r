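test_that("model construction enforces its invariants", {
  feats <- tibble::tibble(label = c("a", "b", "c"), kind = c("ACC", "DON", "HYD"),
                          x = c(0, 3, 6), y = c(0, 1, 0), z = c(0, 0, 1),
                          radius = 1, essential = TRUE, annotation = "")
  m <- ph4_model("ok", feats)
  expect_s3_class(m, "ph4_model")
  expect_error(ph4_model("dup", dplyr::mutate(feats, label = "a")), "unique")
  expect_error(ph4_model("rad", dplyr::mutate(feats, radius = 0)), "> 0")
  expect_error(ph4_model("ess", dplyr::mutate(feats, essential = c(TRUE, TRUE, FALSE))),
               "at least 3")
})

test_that("inter-feature distances are Euclidean, translation-invariant and metric", {
  feats <- tibble::tibble(label = c("a", "b", "c"), kind = c("ACC", "DON", "HYD"),
                          x = c(0, 5, 0), y = c(0, 0, 12), z = 0,
                          radius = 1, essential = TRUE, annotation = "")
  m <- ph4_model("tri", feats)
  dm <- interfeature_distances(m)
  expect_equal(dm["a", "b"], 5)
  expect_equal(diag(dm), c(a = 0, b = 0, c = 0))
  shifted <- ph4_model("tri2", dplyr::mutate(feats, x = x + 7, y = y - 3, z = z + 1))
  expect_equal(unname(interfeature_distances(shifted)), unname(dm))
  # triangle inequality on a random model
  k <- 5
  rf <- tibble::tibble(label = paste0("f", 1:k), kind = "ACC",
                       x = runif(k, 0, 10), y = runif(k, 0, 10),
                       z = runif(k, 0, 10), radius = 1, essential = TRUE,
                       annotation = "")
  dm <- interfeature_distances(ph4_model("rand", rf))
  for (i in 1:k) for (j in 1:k) for (l in 1:k) {
    expect_lte(dm[i, j], dm[i, l] + dm[l, j] + 1e-12)
  }
})

test_that("model JSON serialization round-trips field-identically", {
  for (target in c("vegfr2", "fak")) {
    m <- load_kinase_model(target)
    tmp <- withr::local_tempfile(fileext = ".json")
    write_ph4_json(m, tmp)
    m2 <- read_ph4_json(tmp)
    expect_identical(m2$name, m$name)
    expect_equal(m2$features, m$features)
    expect_equal(m2$exclusions, m$exclusions)
    expect_identical(m2$provenance, m$provenance)
  }
})

test_that("shipped reconstructions carry the published inventory shape", {
  v <- load_kinase_model("vegfr2")
  expect_equal(nrow(v$features), 5)
  expect_equal(nrow(v$exclusions), 378)
  expect_setequal(v$features$kind, c("ACC", "DON_PROJ", "HYD", "ARO"))
  expect_equal(sum(v$features$kind == "ACC"), 2)
  f <- load_kinase_model("fak")
  expect_equal(nrow(f$features), 5)
  expect_equal(nrow(f$exclusions), 68)
  expect_equal(sum(f$features$kind == "HYD"), 2)
  expect_match(f$provenance, "[Ss]ynthetic")
})

test_that("the Pharmer points dialect is importable", {
  tmp <- withr::local_tempfile(fileext = ".json")
  obj <- list(points = list(
    list(name = "HydrogenAcceptor", x = 0, y = 0, z = 0, radius = 1,
         enabled = TRUE),
    list(name = "Hydrophobic", x = 4, y = 0, z = 0, radius = 1.5,
         enabled = TRUE),
    list(name = "Aromatic", x = 2, y = 2, z = 0, radius = 1.1, enabled = TRUE),
    list(name = "HydrogenDonor", x = 1, y = -2, z = 1, radius = 1,
         enabled = FALSE),
    list(name = "ExclusionSphere", x = 9, y = 9, z = 9, radius = 2)))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE)
  m <- read_pharmer_json(tmp)
  expect_equal(nrow(m$features), 3)  # the disabled donor is dropped
  expect_equal(nrow(m$exclusions), 1)
  expect_setequal(m$features$kind, c("ACC", "HYD", "ARO"))
})
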