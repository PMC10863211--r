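# Shared fixtures and independent oracles for the test suite.
# Fixtures are built in code; oracles deliberately avoid the code paths
# they check (bio3d superposition, hand-rolled dynamic programming,
# brute-force enumeration).

# --- small SDF fixtures ------------------------------------------------------

# Benzene with an idealised 3D hexagon (no explicit hydrogens).
benzene_sdf_lines <- function(id = "benzene") {
  r <- 1.39
  ang <- (0:5) * pi / 3
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   r * cos(ang), r * sin(ang), rep(0.05, 6), rep("C", 6))
  bonds <- sprintf("%3d%3d%3d  0", 1:6, c(2:6, 1), rep(c(1, 2), 3))
  c(id, "  test               3D", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000", atoms, bonds, "M  END")
}

write_benzene_sdf <- function(path) {
  writeLines(c(benzene_sdf_lines(), "$$$$"), path)
  path
}

# A deliberately corrupt record (bad counts line).
corrupt_sdf_lines <- function(id = "broken") {
  c(id, "  test", "", "  x  y  0  0999 V2000", "M  END")
}

# Minimal two-chain PDB text (glycine-like stubs).
tiny_pdb_lines <- function() {
  fmt <- "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  c(sprintf(fmt, 1, " N  ", "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    sprintf(fmt, 2, " CA ", "GLY", "A", 1, 1.45, 0.0, 0.0, "C"),
    sprintf(fmt, 3, " C  ", "GLY", "A", 1, 2.0, 1.4, 0.0, "C"),
    sprintf(fmt, 4, " O  ", "GLY", "A", 1, 1.3, 2.4, 0.0, "O"),
    sprintf(fmt, 5, " N  ", "ALA", "B", 1, 5.0, 0.0, 0.0, "N"),
    sprintf(fmt, 6, " CA ", "ALA", "B", 1, 6.45, 0.0, 0.0, "C"),
    sprintf("HETATM%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            7, " C1 ", "LIG", "A", 900, 3.0, 3.0, 3.0, "C"),
    "END")
}

# --- independent oracles -----------------------------------------------------

# Best-fit RMSD via bio3d's superposition (independent implementation;
# the RMSD itself is recomputed at full precision because bio3d::rmsd
# rounds its return value).
oracle_fit_rmsd <- function(p, q) {
  xyz <- bio3d::fit.xyz(fixed = as.vector(t(q)), mobile = as.vector(t(p)),
                        fixed.inds = seq_len(3 * nrow(q)),
                        mobile.inds = seq_len(3 * nrow(p)))
  moved <- matrix(xyz, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((moved - q)^2)))
}

# Exhaustive matcher oracle: all type-respecting injections of the
# model's essential features onto feature-set points, pairwise-distance
# filtered, superposed with bio3d, exclusion-checked on all points.
# Returns list(matched, rmsd).
oracle_match <- function(fs, model, pair_tol = 1.0, rmsd_cutoff = 1.2) {
  feats <- model$features[model$features$essential, , drop = FALSE]
  k <- nrow(feats)
  pts <- as.matrix(fs[, c("x", "y", "z")])
  fcen <- as.matrix(feats[, c("x", "y", "z")])
  fdist <- as.matrix(stats::dist(fcen))
  pdist <- as.matrix(stats::dist(pts))
  cand <- lapply(seq_len(k), function(i) which(fs$kind == feats$kind[i]))
  best <- Inf
  rec <- function(depth, chosen) {
    if (depth > k) {
      p <- pts[chosen, , drop = FALSE]
      if (svd(sweep(p, 2, colMeans(p)))$d[2] < 1e-8) return(invisible())
      if (svd(sweep(fcen, 2, colMeans(fcen)))$d[2] < 1e-8) return(invisible())
      r <- oracle_fit_rmsd(p, fcen)
      if (r <= rmsd_cutoff && r < best) {
        # exclusion check on all points, using bio3d's fitted coords
        if (nrow(model$exclusions)) {
          xyz <- bio3d::fit.xyz(fixed = as.vector(t(fcen)),
                                mobile = as.vector(t(pts)),
                                fixed.inds = atom2xyz(seq_len(k)),
                                mobile.inds = atom2xyz(chosen))
          moved <- matrix(xyz, ncol = 3, byrow = TRUE)
          ex <- model$exclusions
          for (s in seq_len(nrow(ex))) {
            d <- sqrt(rowSums(sweep(moved, 2, c(ex$x[s], ex$y[s], ex$z[s]))^2))
            if (any(d < ex$radius[s] - 1e-12)) return(invisible())
          }
        }
        best <<- r
      }
      return(invisible())
    }
    for (p in cand[[depth]]) {
      if (p %in% chosen) next
      ok <- TRUE
      for (d in seq_len(depth - 1)) {
        if (abs(pdist[p, chosen[d]] - fdist[depth, d]) > pair_tol) {
          ok <- FALSE
          break
        }
      }
      if (ok) rec(depth + 1, c(chosen, p))
    }
  }
  rec(1L, integer(0))
  list(matched = is.finite(best), rmsd = if (is.finite(best)) best else NA_real_)
}

atom2xyz <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))

# Random matcher instance: a small model plus a point cloud that may or
# may not contain a planted copy of the model.
random_match_instance <- function(n_ess = NULL, n_pts = NULL, plant = NULL) {
  n_ess <- n_ess %||% sample(3:5, 1)
  kinds <- sample(c("ACC", "DON", "ARO", "HYD"), n_ess, replace = TRUE)
  centers <- matrix(runif(3 * n_ess, 0, 8), n_ess, 3)
  model <- ph4_model(
    "rand",
    tibble::tibble(label = paste0("F", seq_len(n_ess)), kind = kinds,
                   x = centers[, 1], y = centers[, 2], z = centers[, 3],
                   radius = 1, essential = TRUE, annotation = ""))
  plant <- plant %||% (runif(1) < 0.5)
  pts_kind <- character(0)
  pts <- matrix(numeric(0), 0, 3)
  if (plant) {
    pts_kind <- kinds
    pts <- centers + matrix(rnorm(3 * n_ess, 0, 0.15), n_ess, 3)
  }
  n_pts <- n_pts %||% sample((n_ess + 0):8, 1)
  extra <- max(0, n_pts - nrow(pts))
  if (extra > 0) {
    pts_kind <- c(pts_kind, sample(c("ACC", "DON", "ARO", "HYD"), extra,
                                   replace = TRUE))
    pts <- rbind(pts, matrix(runif(3 * extra, 0, 8), extra, 3))
  }
  tf <- random_rigid_transform(span = 5)
  fs <- feature_set(pts_kind, apply_transform(pts, tf))
  list(model = model, fs = fs, planted = plant)
}

# Affine-gap local alignment score by direct Gotoh dynamic programming
# (independent of the alignment implementation under test).
oracle_sw_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  neg <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1)  # gap in b (deletion)
  Y <- matrix(neg, n + 1, m + 1)  # gap in a (insertion)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) + s)
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
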