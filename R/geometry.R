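# Cartesian geometry primitives: distances, angles, dihedrals (IUPAC sign,
# range (-180, 180]), Kabsch superposition, and internal-to-Cartesian atom
# placement used by the fixture builders and the protonation module.

RAD2DEG <- 180 / pi
DEG2RAD <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Euclidean distance in Angstrom.
#' @export
bond_length <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  vnorm(b - a)
}

#' Valence angle at an apex
#'
#' @param a,b,c Numeric 3-vectors; `b` is the apex.
#' @return Angle a-b-c in degrees, in \[0, 180\].
#' @export
bond_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) stop("degenerate geometry: zero-length angle arm")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * RAD2DEG
}

#' Signed torsion angle
#'
#' Right-handed (IUPAC) convention about the b-c axis: looking from b to c,
#' a positive angle rotates the far bond clockwise from the near bond.
#'
#' @param a,b,c,d Numeric 3-vectors.
#' @return Torsion in degrees, in (-180, 180\].
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate geometry: collinear atoms in torsion")
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / vnorm(b2)
  ang <- atan2(y, x) * RAD2DEG
  if (ang <= -180) ang + 360 else ang
}

#' Wrap an angle into (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * round(x / 360)
  ifelse(w <= -180, w + 360, w)
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame construction: the new atom `d` is put
#' at distance `bond` from `c`, forming angle `angle` (degrees) with b-c and
#' torsion `torsion` (degrees) about b-c relative to `a`.
#'
#' @param a,b,c Numeric 3-vectors defining the frame.
#' @param bond Bond length c-d in Angstrom.
#' @param angle Angle b-c-d in degrees.
#' @param torsion Torsion a-b-c-d in degrees.
#' @return The 3-vector position of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  ang <- angle * DEG2RAD
  tor <- torsion * DEG2RAD
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the r.m.s.d. between
#' two matched coordinate sets, via the singular value decomposition of the
#' cross-covariance matrix with the usual sign correction that excludes
#' reflections.
#'
#' @param reference Numeric matrix n x 3.
#' @param moving Numeric matrix n x 3, same atom order.
#' @return A list with `rmsd` (Angstrom), `rotation` (3 x 3 proper rotation,
#'   det +1) and `translation` (3-vector) such that
#'   `moving %*% t(rotation) + translation` superposes onto `reference`.
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' superpose_rmsd(x, x)$rmsd
#' @export
superpose_rmsd <- function(reference, moving) {
  reference <- as.matrix(reference)
  moving <- as.matrix(moving)
  if (!all(dim(reference) == dim(moving)) || ncol(reference) != 3) {
    stop("coordinate sets must be matched n x 3 matrices")
  }
  n <- nrow(reference)
  if (n < 1) stop("empty coordinate sets")
  cref <- colMeans(reference)
  cmov <- colMeans(moving)
  X <- sweep(reference, 2, cref)
  Y <- sweep(moving, 2, cmov)
  H <- crossprod(Y, X)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)       # x_ref ~ R %*% y_mov
  fitted <- Y %*% t(R)
  rmsd <- sqrt(sum((X - fitted)^2) / n)
  list(rmsd = rmsd, rotation = R,
       translation = as.numeric(cref - R %*% cmov))
}
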