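#' Wrap angles into the Ramachandran convention
#'
#' Maps angles in degrees onto the half-open interval \[-180, 180), the
#' convention used throughout the package for backbone dihedrals. 180 maps to
#' -180 so that every angle has a unique representative.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, in \[-180, 180).
#' @examples
#' wrap_angle(c(185, -180, 180, 0, 359))
#' @export
wrap_angle <- function(x) {
  # identity for in-range values (the modulo arithmetic is not exact at the
  # last bit, and downstream mirror-symmetry identities rely on exactness)
  out <- x
  off <- which(!(x >= -180 & x < 180))
  out[off] <- ((x[off] + 180) %% 360) - 180
  out
}

deg2rad <- function(x) x * (pi / 180)

# Signed dihedral angle (degrees) defined by points a-b-c-d, rows of 3-col
# matrices; used only for geometry self-checks.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Row-wise cross product of n x 3 matrices.
vec_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

vec_norm <- function(a) sqrt(rowSums(a^2))

vec_unit <- function(a) a / vec_norm(a)
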