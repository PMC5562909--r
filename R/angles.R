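#' Wrap angles to the canonical interval [-180, 180)
#'
#' All dihedral descriptors in pemnet live on the half-open interval
#' `[-180, 180)` degrees, so cis is 0 and trans is -180 (a single canonical
#' representative; +180 is excluded). Wrapping an already-wrapped angle is the
#' identity.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, each value in `[-180, 180)`.
#' @examples
#' wrap_angle(c(0, 180, -180, 270, 725))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta)) abort("`theta` must be numeric.")
  ((theta + 180) %% 360) - 180
}

#' Wrapped angular difference
#'
#' Signed circular difference `a - b` mapped to `(-180, 180]` degrees, the
#' convention used by the general distance of the PEM kernel: two dihedrals at
#' +179 and -179 degrees are 2 degrees apart, not 358.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Numeric vector of signed differences in `(-180, 180]`.
#' @examples
#' wrap_angle_diff(179, -179)
#' @export
wrap_angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Signed dihedral (torsion) angle of four points
#'
#' Computes the IUPAC signed torsion a-b-c-d: looking down the b-to-c axis,
#' the angle from the projection of a to the projection of d, clockwise
#' positive. Cis (a and d eclipsed) is 0; trans is 180, reported as -180 under
#' the package's `[-180, 180)` wrapping. Implemented with the projection/atan2
#' formulation, which is numerically stable near 0 and 180.
#'
#' @param a,b,c,d Numeric 3-vectors, Cartesian coordinates in Angstrom.
#' @return Angle in degrees in `[-180, 180)`.
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # cis: 0
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # +90
#' @export
dihedral_angle <- function(a, b, c, d) {
  for (v in list(a, b, c, d)) {
    if (length(v) != 3L || !all(is.finite(v))) {
      abort("dihedral_angle() needs four finite 3-vectors.")
    }
  }
  b0 <- a - b
  b1 <- c - b
  b2 <- d - c
  nb1 <- sqrt(sum(b1^2))
  if (nb1 < 1e-10 || sqrt(sum(b0^2)) < 1e-10 || sqrt(sum(b2^2)) < 1e-10) {
    abort("Degenerate dihedral: coincident consecutive points.")
  }
  b1 <- b1 / nb1
  # components of the outer bonds perpendicular to the central axis
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (sum(v^2) < 1e-20 || sum(w^2) < 1e-20) {
    abort("Degenerate dihedral: bond parallel to the central b-c axis.")
  }
  x <- sum(v * w)
  y <- sum(cross3(b1, v) * w)
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

#' Build a polymer-like chain realizing prescribed torsion angles
#'
#' Places `length(torsions) + 3` atoms sequentially (natural extension
#' reference frame): fixed bond lengths and bond angles, with atom `i + 3`
#' placed so the torsion over atoms `(i, i+1, i+2, i+3)` equals `torsions[i]`.
#' Used by the synthetic-data generator to embed sampled dihedral descriptors
#' into Cartesian frames, and handy for constructing geometries with known
#' torsions in tests.
#'
#' @param torsions Numeric vector of torsion angles, degrees.
#' @param bond_length Bond length in Angstrom (default 1.5).
#' @param bond_angle Bond angle in degrees (default 109.5).
#' @return Numeric matrix `(length(torsions) + 3) x 3` of coordinates.
#' @examples
#' xyz <- chain_from_torsions(c(37, -120))
#' dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
#' @export
chain_from_torsions <- function(torsions, bond_length = 1.5, bond_angle = 109.5) {
  if (length(torsions) < 1L || !all(is.finite(torsions))) {
    abort("`torsions` must be a non-empty finite numeric vector.")
  }
  if (bond_length <= 0) abort("`bond_length` must be positive.")
  n <- length(torsions) + 3L
  xyz <- matrix(0, n, 3L)
  ang <- bond_angle * pi / 180
  xyz[2L, ] <- c(bond_length, 0, 0)
  xyz[3L, ] <- xyz[2L, ] + bond_length * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_along(torsions)) {
    xyz[i + 3L, ] <- place_atom(
      xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ],
      bond_length, ang, torsions[i] * pi / 180
    )
  }
  xyz
}

# place D given A, B, C with |CD| = r, angle BCD = theta, torsion ABCD = phi
place_atom <- function(a, b, c, r, theta, phi) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
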