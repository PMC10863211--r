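test_that("benzene perception places one aromatic centroid", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_benzene_sdf(path)
  bz <- read_sdf(path)[[1]]
  fs <- perceive_features(bz)
  aro <- fs[fs$kind == "ARO", ]
  expect_equal(nrow(aro), 1)
  centroid <- colMeans(bz$conformers[[1]])
  expect_lt(max(abs(c(aro$x, aro$y, aro$z) - centroid)), 1e-6)
})

test_that("urea fragments present acceptor oxygen and two donor nitrogens", {
  # diphenylurea-like core, the classic type II hinge/gate chemotype
  m <- generate_conformers(parse_smiles("c1ccccc1NC(=O)Nc1ccccc1", "dpu")[[1]],
                           n = 1, seed = 3)
  fs <- perceive_features(m)
  o_idx <- which(m$atoms$element == "O")
  acc <- fs[fs$kind == "ACC", ]
  expect_true(any(vapply(acc$source_atoms, function(s) o_idx %in% s,
                         logical(1))))
  don <- fs[fs$kind == "DON", ]
  n_idx <- which(m$atoms$element == "N")
  don_atoms <- unlist(don$source_atoms)
  expect_true(all(n_idx %in% don_atoms))
  # amide nitrogens do not act as acceptors
  expect_false(any(n_idx %in% unlist(acc$source_atoms)))
})

test_that("ACC/DON sit on heavy atoms; ARO/HYD are source centroids", {
  lib <- gen_molecule_library(15, seed = 21)
  emb <- embed_library(lib, n = 1, seed = 77)
  for (m in emb$molecules) {
    if (isTRUE(attr(m, "embed_failed"))) next
    fs <- perceive_features(m)
    coords <- m$conformers[[1]]
    for (k in seq_len(nrow(fs))) {
      pos <- c(fs$x[k], fs$y[k], fs$z[k])
      src <- fs$source_atoms[[k]]
      if (fs$kind[k] %in% c("ACC", "DON")) {
        expect_lt(sqrt(sum((pos - coords[src[1], ])^2)), 1e-9)
      } else if (fs$kind[k] %in% c("ARO", "HYD")) {
        expect_lt(sqrt(sum((pos - colMeans(coords[src, , drop = FALSE]))^2)),
                  1e-9)
      }
    }
  }
})

test_that("perception is equivariant under rigid motion", {
  m <- generate_conformers(parse_smiles("CC(=O)Nc1ccc(O)cc1", "apap")[[1]],
                           n = 1, seed = 11)
  fs <- perceive_features(m)
  for (rep in 1:5) {
    tf <- random_rigid_transform()
    m2 <- m
    m2$conformers[[1]] <- apply_transform(m$conformers[[1]], tf)
    fs2 <- perceive_features(m2)
    expect_equal(sort(fs2$kind), sort(fs$kind))
    moved <- apply_transform(as.matrix(fs[, c("x", "y", "z")]), tf)
    got <- as.matrix(fs2[, c("x", "y", "z")])
    # deterministic sorting reorders points within a kind under rotation;
    # compare as a bijection of nearest neighbours within each kind
    for (kind in unique(fs$kind)) {
      a <- moved[fs$kind == kind, , drop = FALSE]
      b <- got[fs2$kind == kind, , drop = FALSE]
      expect_equal(nrow(a), nrow(b))
      used <- rep(FALSE, nrow(b))
      for (i in seq_len(nrow(a))) {
        dists <- sqrt(rowSums(sweep(b, 2, a[i, ])^2))
        dists[used] <- Inf
        j <- which.min(dists)
        expect_lt(dists[j], 1e-6)
        used[j] <- TRUE
      }
    }
  }
})

test_that("donor projection has closed-form geometry", {
  p <- project_donor(c(0, 0, 0), c(1, 0, 0), distance = 2.8)
  expect_equal(c(p$x, p$y, p$z), c(2.8, 0, 0))
  p0 <- project_donor(c(1, 2, 3), c(1, 3, 3), distance = 0)
  expect_equal(c(p0$x, p0$y, p0$z), c(1, 2, 3))
  expect_error(project_donor(c(0, 0, 0), c(0, 0, 0)), "zero-length")
  for (rep in 1:20) {
    d <- runif(3, -5, 5)
    h <- d + rnorm(3)
    dist <- runif(1, 0.5, 4)
    pr <- project_donor(d, h, dist)
    expect_lt(abs(sqrt(sum((c(pr$x, pr$y, pr$z) - d)^2)) - dist), 1e-9)
  }
})

test_that("the rule dictionary is editable and drives perception", {
  rules <- read_feature_rules()
  expect_true(all(c("ACC", "DON", "ARO", "HYD") %in% rules$kind))
  # disabling HYD removes hydrophobic points
  no_hyd <- rules[rules$kind != "HYD", ]
  m <- generate_conformers(parse_smiles("CCCCc1ccccc1", "bb")[[1]],
                           n = 1, seed = 2)
  fs_full <- perceive_features(m)
  fs_cut <- perceive_features(m, rules = no_hyd)
  expect_gt(sum(fs_full$kind == "HYD"), 0)
  expect_equal(sum(fs_cut$kind == "HYD"), 0)
})
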