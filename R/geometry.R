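# Rigid-body geometry primitives shared by rotamer construction, pose
# sampling and RMSD evaluation. All coordinates in Angstrom, angles in
# degrees (package-wide convention).

DEG <- pi / 180

#' Measure a proper dihedral angle
#'
#' Returns the torsion angle defined by four points, following the IUPAC
#' sign convention, in degrees within (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions, returns the point `d` with bond length
#' |d - c| = `bond`, bond angle b-c-d = `angle` and proper dihedral
#' a-b-c-d = `torsion`.
#'
#' @param a,b,c Numeric 3-vectors: torsion reference, angle reference and
#'   the atom the new atom is bonded to.
#' @param bond Bond length, Angstrom.
#' @param angle Bond angle in degrees.
#' @param torsion Dihedral in degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * DEG
  ph <- torsion * DEG
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rodrigues rotation of point rows `xyz` (n x 3) about the axis through
# `origin` with direction `axis`, by `theta` degrees.
rotate_about_axis <- function(xyz, origin, axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta * DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# Intrinsic x -> y -> z Euler rotation matrix (degrees). Applied to column
# coordinate vectors as R %*% v.
euler_xyz_matrix <- function(rx, ry, rz) {
  cx <- cos(rx * DEG); sx <- sin(rx * DEG)
  cy <- cos(ry * DEG); sy <- sin(ry * DEG)
  cz <- cos(rz * DEG); sz <- sin(rz * DEG)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# All pairwise distances between two n x 3 / m x 3 coordinate matrices.
cross_dist <- function(xyz_a, xyz_b) {
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * tcrossprod(xyz_a, xyz_b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `mobile` onto `fixed` using the point subsets given by
#' `fit_fixed` / `fit_mobile` (defaults: all points), then applies the
#' fitted rigid transform to every mobile point.
#'
#' @param fixed,mobile n x 3 coordinate matrices.
#' @param fit_fixed,fit_mobile Row indices used to fit the transform; the
#'   two index vectors must have equal length >= 3.
#' @return The transformed `mobile` matrix.
#' @export
kabsch_superpose <- function(fixed, mobile, fit_fixed = seq_len(nrow(fixed)),
                             fit_mobile = seq_len(nrow(mobile))) {
  stopifnot(length(fit_fixed) == length(fit_mobile), length(fit_fixed) >= 3)
  A <- fixed[fit_fixed, , drop = FALSE]
  B <- mobile[fit_mobile, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mobile, 2, cb) %*% t(R), 2, ca, "+")
}
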