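# Rigid-body geometry: Kabsch superposition, rotations, internal-coordinate
# atom placement (NeRF). All coordinates in Angstrom, angles in degrees at the
# user surface and radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be normalized).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  c1 <- cos(th); s1 <- sin(th); t1 <- 1 - c1
  matrix(c(
    c1 + u[1]^2 * t1,        u[1] * u[2] * t1 - u[3] * s1, u[1] * u[3] * t1 + u[2] * s1,
    u[2] * u[1] * t1 + u[3] * s1, c1 + u[2]^2 * t1,        u[2] * u[3] * t1 - u[1] * s1,
    u[3] * u[1] * t1 - u[2] * s1, u[3] * u[2] * t1 + u[1] * s1, c1 + u[3]^2 * t1
  ), nrow = 3, byrow = TRUE)
}

#' Closed-form least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum_i ||R x_i + t - y_i||^2 for paired coordinates. Reflections are
#' excluded: the returned rotation always has determinant +1.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates.
#' @return list with `rotation` (3x3), `translation` (length-3), and `rmsd`
#'   after superposition.
#' @export
kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference))
  if (nrow(mobile) < 3) abort("superposition needs at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  dimnames(R) <- NULL
  t_vec <- unname(cr - as.numeric(R %*% cm))
  moved <- sweep(mobile %*% t(R), 2, t_vec, "+")
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param tr list with `rotation` and `translation` (as from [kabsch()]).
#' @return transformed n x 3 matrix.
#' @export
transform_xyz <- function(xyz, tr) {
  sweep(xyz %*% t(tr$rotation), 2, tr$translation, "+")
}

transform_atoms <- function(atoms, tr) {
  set_coords(atoms, transform_xyz(coords(atoms), tr))
}

identity_transform <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0))
}

#' Angle at atom b in degrees
#' @param a,b,c 3-vectors.
#' @return angle in degrees.
#' @export
angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Dihedral angle a-b-c-d in degrees, in (-180, 180]
#' @param a,b,c,d 3-vectors.
#' @return signed dihedral in degrees.
#' @export
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions a-b-c, place atom d with bond length
#' |c-d|, angle b-c-d and dihedral a-b-c-d.
#'
#' @param a,b,c reference positions (3-vectors).
#' @param bond bond length c-d in Angstrom.
#' @param angle angle b-c-d in degrees.
#' @param dihedral dihedral a-b-c-d in degrees.
#' @return position of d (3-vector).
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  unname(c + d2[1] * bc + d2[2] * m + d2[3] * n)
}

#' Pairwise distance matrix between two coordinate sets
#' @param a n x 3 matrix. @param b m x 3 matrix (defaults to `a`).
#' @return n x m matrix of Euclidean distances in Angstrom.
#' @export
dist_xyz <- function(a, b = a) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
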