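# The matching engine against closed-form cases and brute-force oracles.

simple_model <- function(exclusions = NULL) {
  ph4_model("m4", tibble::tibble(
    label = c("F1", "F2", "F3", "F4"),
    kind = c("ACC", "DON", "HYD", "ARO"),
    x = c(0, 4, 8, 3), y = c(0, 1, -1, 4), z = c(0, 0.5, 1, -0.5),
    radius = 1, essential = c(TRUE, TRUE, TRUE, FALSE), annotation = ""),
    exclusions = exclusions)
}

test_that("kabsch recovers exact and noisy superpositions", {
  set.seed(1)
  p <- matrix(rnorm(15, sd = 3), 5, 3)
  expect_equal(kabsch(p, p)$rmsd, 0)
  for (rep in 1:10) {
    tf <- random_rigid_transform()
    q <- apply_transform(p, tf)
    fit <- kabsch(p, q)
    expect_lt(fit$rmsd, 1e-9)
    expect_lt(max(abs(apply_transform(p, fit) - q)), 1e-9)
    # independent oracle: bio3d best-fit rmsd agrees on noisy pairs
    qn <- q + matrix(rnorm(15, sd = 0.3), 5, 3)
    expect_lt(abs(kabsch(p, qn)$rmsd - oracle_fit_rmsd(p, qn)), 1e-6)
  }
})

test_that("correspondence enumeration applies type and distance prefilters", {
  m <- simple_model()
  # all essential centers present -> identity-compatible mapping found
  fs <- feature_set(m$features$kind, as.matrix(m$features[, c("x", "y", "z")]))
  cands <- enumerate_correspondences(fs, m, pair_tol = 1.0)
  expect_gte(length(cands), 1)
  rmsds <- vapply(cands, function(cc) align_and_score(fs, cc, m)$rmsd,
                  numeric(1))
  expect_lt(min(rmsds), 1e-9)
  # missing essential kind -> empty candidate list
  fs_miss <- feature_set(c("DON", "HYD", "ARO"),
                         as.matrix(m$features[2:4, c("x", "y", "z")]))
  expect_length(enumerate_correspondences(fs_miss, m, 1.0), 0)
})

test_that("enumeration equals brute force over type-respecting injections", {
  set.seed(42)
  for (rep in 1:30) {
    inst <- random_match_instance()
    cands <- enumerate_correspondences(inst$fs, inst$model, pair_tol = 1.0)
    # brute force count: recursion in the oracle enumerates the same set
    feats <- inst$model$features
    k <- nrow(feats)
    pts <- as.matrix(inst$fs[, c("x", "y", "z")])
    fdist <- as.matrix(stats::dist(as.matrix(feats[, c("x", "y", "z")])))
    pdist <- as.matrix(stats::dist(pts))
    count <- 0
    rec <- function(depth, chosen) {
      if (depth > k) { count <<- count + 1; return(invisible()) }
      for (p in which(inst$fs$kind == feats$kind[depth])) {
        if (p %in% chosen) next
        ok <- all(vapply(seq_len(depth - 1), function(d)
          abs(pdist[p, chosen[d]] - fdist[depth, d]) <= 1.0, logical(1)))
        if (ok) rec(depth + 1, c(chosen, p))
      }
    }
    rec(1L, integer(0))
    expect_equal(length(cands), count)
  }
})

test_that("alignment scores exact poses at zero and rejects degenerate sets", {
  m <- simple_model()
  fs <- feature_set(m$features$kind, as.matrix(m$features[, c("x", "y", "z")]))
  cand <- enumerate_correspondences(fs, m, 1.0)[[1]]
  fit <- align_and_score(fs, cand, m)
  expect_lt(fit$rmsd, 1e-9)
  # collinear conformer points -> informative error
  col_m <- ph4_model("col", tibble::tibble(
    label = c("a", "b", "c"), kind = "ACC",
    x = c(0, 2, 7), y = c(0, 1, 0), z = 0,
    radius = 1, essential = TRUE, annotation = ""))
  fs_col <- feature_set(c("ACC", "ACC", "ACC"),
                        matrix(c(0, 0, 0, 1, 0, 0, 5, 0, 0), 3, 3, byrow = TRUE))
  cand <- list(essential = setNames(1:3, c("a", "b", "c")), optional = integer(0))
  expect_error(align_and_score(fs_col, cand, col_m), "collinear")
})

test_that("exclusion checks follow the strict-interior rule", {
  m0 <- simple_model()
  fs <- feature_set(m0$features$kind, as.matrix(m0$features[, c("x", "y", "z")]))
  res0 <- match_pharmacophore(fs, m0)
  expect_true(res0$matched)
  idm <- list(rotation = diag(3), translation = c(0, 0, 0))
  # no exclusions -> always pass
  expect_true(check_exclusions(feature_coords(fs), idm, m0)$pass)
  # sphere centered on a mapped point, radius 1 -> clash
  m1 <- simple_model(exclusions = tibble::tibble(x = 0, y = 0, z = 0, radius = 1))
  ex <- check_exclusions(feature_coords(fs), idm, m1)
  expect_false(ex$pass)
  expect_equal(ex$clashes$sphere, 1L)
  # shrinking the radius below the nearest point distance flips a
  # clashing probe sphere to pass
  probe <- c(1, 1, 1)
  dmin <- min(sqrt(rowSums(sweep(feature_coords(fs), 2, probe)^2)))
  m_clash <- simple_model(exclusions = tibble::tibble(
    x = probe[1], y = probe[2], z = probe[3], radius = dmin + 0.1))
  expect_false(check_exclusions(feature_coords(fs), idm, m_clash)$pass)
  m2 <- simple_model(exclusions = tibble::tibble(
    x = probe[1], y = probe[2], z = probe[3], radius = dmin - 0.1))
  expect_true(check_exclusions(feature_coords(fs), idm, m2)$pass)
})

test_that("match result fields respect the fixture contract", {
  m <- simple_model()
  fs <- feature_set(m$features$kind, as.matrix(m$features[, c("x", "y", "z")]),
                    molecule_id = "perfect")
  res <- match_pharmacophore(fs, m)
  expect_true(res$matched)
  expect_lt(res$rmsd, 1e-9)
  expect_equal(res$n_optional, 1L)
  fs_miss <- feature_set(c("DON", "HYD"), matrix(rnorm(6), 2, 3),
                         molecule_id = "typeless")
  res2 <- match_pharmacophore(fs_miss, m)
  expect_false(res2$matched)
  expect_identical(res2$reason, "no correspondence")
})

test_that("match equals the exhaustive oracle on random instances", {
  set.seed(7)
  n_agree <- 0
  for (rep in 1:60) {
    inst <- random_match_instance()
    mine <- match_pharmacophore(inst$fs, inst$model, pair_tol = 1.0,
                                rmsd_cutoff = 1.2)
    orc <- oracle_match(inst$fs, inst$model, pair_tol = 1.0, rmsd_cutoff = 1.2)
    expect_identical(mine$matched, orc$matched)
    if (mine$matched) expect_lt(abs(mine$rmsd - orc$rmsd), 1e-6)
    n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 60)
})

test_that("matching is invariant under rigid motion of the conformer", {
  set.seed(13)
  m <- simple_model()
  base <- feature_set(m$features$kind,
                      as.matrix(m$features[, c("x", "y", "z")]) +
                        matrix(rnorm(12, 0, 0.2), 4, 3))
  ref <- match_pharmacophore(base, m)
  for (rep in 1:20) {
    tf <- random_rigid_transform()
    moved <- feature_set(base$kind, apply_transform(feature_coords(base), tf))
    res <- match_pharmacophore(moved, m)
    expect_identical(res$matched, ref$matched)
    expect_lt(abs(res$rmsd - ref$rmsd), 1e-6)
  }
})

test_that("adding exclusions is monotone and optional features never gate", {
  set.seed(99)
  for (rep in 1:20) {
    inst <- random_match_instance(plant = TRUE)
    res_free <- match_pharmacophore(inst$fs, inst$model)
    sphere <- tibble::tibble(x = runif(1, 0, 8), y = runif(1, 0, 8),
                             z = runif(1, 0, 8), radius = runif(1, 0.5, 2))
    m_ex <- ph4_model(inst$model$name, inst$model$features, sphere)
    res_ex <- match_pharmacophore(inst$fs, m_ex)
    # FALSE can never flip to TRUE by adding an exclusion
    expect_false(!res_free$matched && res_ex$matched)
  }
  # dropping an optional feature leaves the matched set intact
  m <- simple_model()
  m_no_opt <- ph4_model("no_opt", m$features[m$features$essential, ])
  fix <- gen_feature_fixtures(m, n_active = 15, n_decoy = 30,
                              noise_sd = 0.2, seed = 5)
  full <- vapply(fix$features, function(f) match_pharmacophore(f, m)$matched,
                 logical(1))
  cut <- vapply(fix$features, function(f) match_pharmacophore(f, m_no_opt)$matched,
                logical(1))
  expect_gte(sum(cut), sum(full))
})
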