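# Hydrogen-bond geometry, type II pattern validation and Calpha
# superposition on constructed complexes with known ground truth.

test_that("toy-complex hydrogen bonds respect distance and angle criteria", {
  tc <- gen_toy_complex(d_hbond = 2.9, angle = 170, n_contacts = 5, seed = 1)
  spec <- read_target_spec("fak")
  residues <- unname(spec$key_residues)
  hb <- detect_hbonds(tc$ligand, tc$protein, residues)
  expect_gte(nrow(hb), 3)
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(is.na(hb$angle) | hb$angle >= 120))
  # same geometry at 4.0 A: nothing within criteria
  tc4 <- gen_toy_complex(d_hbond = 4.0, angle = 170, n_contacts = 5, seed = 1)
  expect_equal(nrow(detect_hbonds(tc4$ligand, tc4$protein, residues)), 0)
  # unknown residue -> error naming it
  expect_error(detect_hbonds(tc$ligand, tc$protein,
                             list(list(chain = "A", resno = 999, resid = "GLY"))),
               "999")
})

test_that("the realized bond geometry equals the planted parameters", {
  residues <- unname(read_target_spec("fak")$key_residues)
  tags <- c("CYS502", "ASP564", "GLU471")
  for (d in c(2.6, 3.0, 3.4)) {
    for (ang in c(130, 150, 175)) {
      tc <- gen_toy_complex(d_hbond = d, angle = ang, n_contacts = 4, seed = 2)
      hb <- detect_hbonds(tc$ligand, tc$protein, residues,
                          d_max = 5, angle_min = 0)
      # each key residue carries a bond with exactly the planted geometry
      for (tag in tags) {
        sub <- hb[hb$residue == tag, ]
        expect_true(any(abs(sub$distance - d) < 1e-6 &
                          abs(sub$angle - ang) < 1e-4),
                    label = sprintf("%s d=%.1f ang=%.0f", tag, d, ang))
      }
    }
  }
})

test_that("detection boundary equals the configured criteria exactly", {
  spec <- read_target_spec("fak")
  residues <- unname(spec$key_residues)
  grid <- expand.grid(d = c(3.3, 3.5, 3.7), ang = c(110, 120, 150))
  for (k in seq_len(nrow(grid))) {
    tc <- gen_toy_complex(d_hbond = grid$d[k], angle = grid$ang[k],
                          n_contacts = 3, seed = 3)
    hb <- detect_hbonds(tc$ligand, tc$protein, residues,
                        d_max = 3.5, angle_min = 120)
    should <- grid$d[k] <= 3.5 && grid$ang[k] >= 120
    expect_identical(nrow(hb) > 0, should,
                     label = sprintf("d=%.1f ang=%.0f", grid$d[k], grid$ang[k]))
  }
})

test_that("type II validation pass/fail equals planted truth over a sweep", {
  set.seed(4)
  spec <- read_target_spec("fak")
  for (rep in 1:20) {
    d <- runif(1, 2.5, 4.2)
    ang <- runif(1, 100, 180)
    nc <- sample(0:6, 1)
    tc <- gen_toy_complex(d_hbond = d, angle = ang, n_contacts = nc,
                          seed = rep)
    v <- validate_type2(tc$ligand, tc$protein, spec)
    expect_identical(v$type2_pass, tc$truth$expected_pass,
                     label = sprintf("d=%.2f ang=%.0f nc=%d", d, ang, nc))
  }
})

test_that("a deleted hinge bond fails validation and is named", {
  tc <- gen_toy_complex(2.9, 170, 5, seed = 6)
  spec <- read_target_spec("fak")
  # move the ligand acceptor far from the hinge nitrogen
  lig <- tc$ligand
  lig$conformers[[1]][1, ] <- c(50, 50, 50)
  v <- validate_type2(lig, tc$protein, spec)
  expect_false(v$type2_pass)
  hinge <- v$per_residue[v$per_residue$role == "hinge", ]
  expect_false(hinge$satisfied)
  expect_match(hinge$residue, "CYS502")
})

test_that("superposition recovers identity and rigid motions", {
  tc <- gen_toy_complex(2.9, 170, 5, seed = 8)
  prot <- tc$protein
  # give every residue a CA to align on
  ca <- prot$atoms[prot$atoms$elety == "CA", ]
  pairs <- tibble::tibble(resno_a = c(502, 564, 471, 567),
                          resno_b = c(502, 564, 471, 567))
  # self: add CA atoms for residues lacking one
  add_ca <- function(p) {
    for (rn in c(564, 471, 567)) {
      sub <- p$atoms[p$atoms$resno == rn, ][1, ]
      sub$elety <- "CA"; sub$element <- "C"
      p$atoms <- dplyr::bind_rows(p$atoms, sub)
    }
    p
  }
  prot <- add_ca(prot)
  self <- superpose(prot, prot, pairs)
  expect_lt(self$ca_rmsd, 1e-12)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)
  tf <- random_rigid_transform()
  moved <- prot
  xyz <- apply_transform(as.matrix(prot$atoms[, c("x", "y", "z")]), tf)
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  fit <- superpose(prot, moved, pairs)
  expect_lt(fit$ca_rmsd, 1e-9)
  expect_error(superpose(prot, prot, pairs[1:2, ]), "3 aligned")
})

test_that("noisy-copy superposition rmsd matches the analytic expectation", {
  # for n pairs with isotropic Gaussian noise sd s, the best-fit rmsd
  # concentrates near s * sqrt(3) * sqrt(1 - 2/n) once n >> 3
  set.seed(9)
  n <- 60
  s <- 0.5
  base <- matrix(runif(3 * n, 0, 40), n, 3)
  atoms <- tibble::tibble(chain = "A", resno = seq_len(n), ins = "",
                          resid = "ALA", elety = "CA", element = "C",
                          x = base[, 1], y = base[, 2], z = base[, 3],
                          het = FALSE)
  prot_a <- new_protein(atoms)
  rmsds <- replicate(30, {
    noisy <- base + matrix(rnorm(3 * n, 0, s), n, 3)
    b <- prot_a
    b$atoms$x <- noisy[, 1]; b$atoms$y <- noisy[, 2]; b$atoms$z <- noisy[, 3]
    superpose(prot_a, b, tibble::tibble(resno_a = seq_len(n),
                                        resno_b = seq_len(n)))$ca_rmsd
  })
  expected <- s * sqrt(3) * sqrt(1 - 2 / n)
  expect_lt(abs(mean(rmsds) - expected) / expected, 0.1)
})
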