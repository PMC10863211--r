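# Rigid-body geometry shared by the matcher, superposition and the
# interaction validator.  Coordinates are n x 3 matrices in Angstrom.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Computes the rotation and translation that minimise the root mean
#' square deviation between paired point sets, i.e. the transform `T`
#' with `T(P) ~ Q` in the least-squares sense.
#'
#' @param p,q Numeric matrices of matching dimension (n x 3): `p` is the
#'   moving set, `q` the reference.
#' @return A list with elements `rotation` (3 x 3 matrix), `translation`
#'   (length-3 vector), and `rmsd` (Angstrom). The transform acts as
#'   `x %*% t(rotation) + translation`.
#' @examples
#' p <- matrix(rnorm(12), 4, 3)
#' kabsch(p, p)$rmsd  # 0
#' @export
kabsch <- function(p, q) {
  stopifnot(is.matrix(p), is.matrix(q), ncol(p) == 3, ncol(q) == 3,
            nrow(p) == nrow(q), nrow(p) >= 1)
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  h <- crossprod(pc, qc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  dd <- diag(c(1, 1, d))
  rot <- sv$v %*% dd %*% t(sv$u)
  tr <- cq - as.vector(rot %*% cp)
  moved <- pc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - qc)^2)))
  list(rotation = rot, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform List with `rotation` and `translation` as returned
#'   by [kabsch()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Random rigid motion
#'
#' Draws a uniformly random rotation (via QR decomposition of a Gaussian
#' matrix with sign fix) and a translation with coordinates uniform on
#' `[-span, span]`. Used by the generators and the invariance tests.
#'
#' @param span Half-width of the translation cube in Angstrom.
#' @return List with `rotation` and `translation`.
#' @export
random_rigid_transform <- function(span = 10) {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  rot <- rot %*% diag(sign(diag(qr.R(qr_))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rotation = rot, translation = runif(3, -span, span))
}

# Angle D-H...A at the hydrogen, in degrees.
hba_angle <- function(donor, hydrogen, acceptor) {
  v1 <- donor - hydrogen
  v2 <- acceptor - hydrogen
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# Second singular value of the centred point set; ~0 means collinear.
collinearity_gap <- function(coords) {
  if (nrow(coords) < 3) return(0)
  svd(sweep(coords, 2, colMeans(coords)))$d[2]
}
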