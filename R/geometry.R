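# Low-level 3D geometry used throughout: vector helpers, internal-coordinate
# atom placement (NeRF), dihedrals and Kabsch least-squares superposition.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(v * 0)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame (NeRF) placement: given three previously
#' placed atoms `a`-`b`-`c`, returns the position of a fourth atom `d` with
#' bond length `|c-d|`, bond angle `b-c-d` and torsion `a-b-c-d`.
#'
#' @param a,b,c numeric xyz of the three frame atoms.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param torsion dihedral angle in degrees.
#' @return numeric xyz of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric xyz coordinates.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * unit(b2))
  atan2(y, x) * 180 / pi
}

# Random rigid motion, used by invariance tests and fixtures.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (vnorm(q) > 1e-6) break
  }
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
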