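# Small 3D geometry kernel shared by the helix detector and the fixture
# generator. All angles in degrees, all lengths in Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle about the p2-p3 axis, IUPAC convention, in degrees
#' in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return numeric scalar, degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural extension reference frame (NeRF) placement: position atom D given
# the positions of A, B, C, the C-D bond length, the B-C-D angle and the
# A-B-C-D torsion.
place_atom <- function(a, b, c, length, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180  # frame below traces torsions left-handed
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Rotation matrix for a rotation of theta degrees about a unit axis.
rotmat_axis_angle <- function(axis, theta_deg) {
  u <- unitv(axis)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Rotation carrying unit vector `from` onto unit vector `to`.
rotmat_between <- function(from, to) {
  f <- unitv(from); t <- unitv(to)
  v <- vcross(f, t)
  s <- vnorm(v)
  c_ <- sum(f * t)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    perp <- vcross(f, c(1, 0, 0))
    if (vnorm(perp) < 1e-6) perp <- vcross(f, c(0, 1, 0))
    return(rotmat_axis_angle(perp, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               nrow = 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}
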