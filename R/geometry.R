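# Internal 3-D geometry helpers: NeRF atom placement, dihedral/angle
# measurement, rotation constructors.  All angles in degrees, lengths in
# Angstrom, coordinates as length-3 numeric vectors or m x 3 matrices with
# one point per row.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D given the three preceding atoms A-B-C, the C-D bond length,
# the B-C-D bond angle and the A-B-C-D dihedral (natural extension
# reference frame).
nerf_place <- function(a, b, c, length, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- length * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Signed dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

bond_angle <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2)
  v2 <- unit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

# Rotation matrix about a (unit) axis by an angle (Rodrigues). Acts on
# column vectors; row-vector coordinates use X %*% t(R).
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Uniform random rotation via normalized quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    3, 3, byrow = TRUE)
}

is_orthonormal <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol
}

# Apply rigid transform to row-coordinate matrix: X R^T + t.
apply_transform <- function(X, R, t) {
  Y <- tcrossprod(X, R)
  Y[, 1] <- Y[, 1] + t[1]
  Y[, 2] <- Y[, 2] + t[2]
  Y[, 3] <- Y[, 3] + t[3]
  Y
}

# Random point uniform in a ball of given radius.
runif_ball <- function(radius) {
  repeat {
    p <- runif(3, -1, 1)
    if (sum(p * p) <= 1) return(p * radius)
  }
}
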