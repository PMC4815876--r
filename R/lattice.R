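# Core unit-cell / basis algebra. Convention: bases are stored as rows
# (row 1 = a, row 2 = b, row 3 = c); a reciprocal lattice point is g = h %*% B
# with h an integer row vector, and A %*% t(B) = I (crystallographic 1/d
# convention, no 2*pi factor). Angles are degrees at the interface, radians
# internally.

.deg2rad <- function(x) x * pi / 180

# argument under the square root of the triclinic volume formula
.volumeArg <- function(alpha, beta, gamma) {
  ca <- cos(.deg2rad(alpha)); cb <- cos(.deg2rad(beta)); cg <- cos(.deg2rad(gamma))
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Unit-cell volume
#'
#' Computes `V = a b c sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#' + 2 cos(alpha) cos(beta) cos(gamma))`.
#'
#' @param cell A [UnitCell-class].
#' @return Volume in cubic Angstrom.
#' @examples
#' cellVolume(UnitCell(4.51, 5.05, 6.73))  # orthorhombic cementite, 153.28
#' @export
cellVolume <- function(cell) {
  stopifnot(methods::is(cell, "UnitCell"))
  arg <- .volumeArg(cell@alpha, cell@beta, cell@gamma)
  if (arg <= 0) stop("invalid cell: non-positive volume argument")
  cell@a * cell@b * cell@c * sqrt(arg)
}

#' Direct basis from cell parameters
#'
#' Builds a 3 x 3 direct basis (rows = lattice vectors, Angstrom) in the
#' standard setting: `a` along x, `b` in the x-y plane with positive y
#' component, `c` completing a right-handed set. `|det|` equals the cell
#' volume.
#'
#' @param cell A [UnitCell-class].
#' @return 3 x 3 numeric matrix.
#' @export
directBasisFromCell <- function(cell) {
  stopifnot(methods::is(cell, "UnitCell"))
  methods::validObject(cell)
  ca <- cos(.deg2rad(cell@alpha)); cb <- cos(.deg2rad(cell@beta))
  cg <- cos(.deg2rad(cell@gamma)); sg <- sin(.deg2rad(cell@gamma))
  v <- sqrt(.volumeArg(cell@alpha, cell@beta, cell@gamma))
  rbind(c(cell@a, 0, 0),
        c(cell@b * cg, cell@b * sg, 0),
        c(cell@c * cb, cell@c * (ca - cb * cg) / sg, cell@c * v / sg))
}

#' Reciprocal basis
#'
#' The inverse-transpose of a direct basis: `A %*% t(B) = I`, so reciprocal
#' lattice points are `g = h %*% B` for integer rows `h`.
#'
#' @param direct 3 x 3 direct basis (rows = lattice vectors, Angstrom).
#' @return 3 x 3 reciprocal basis (rows = a*, b*, c*, 1/Angstrom).
#' @export
reciprocalBasis <- function(direct) {
  d <- det(direct)
  if (!is.finite(d) || abs(d) < 1e-12) stop("singular basis")
  t(solve(direct))
}

#' Cell parameters from a direct basis
#'
#' Row norms give the lengths; pairwise angles give alpha (b,c), beta (a,c),
#' gamma (a,b). Invariant under any rotation of the basis.
#'
#' @param direct 3 x 3 direct basis (rows = lattice vectors, Angstrom).
#' @return A [UnitCell-class].
#' @export
cellFromBasis <- function(direct) {
  d <- det(direct)
  if (!is.finite(d) || abs(d) < 1e-12) stop("singular basis")
  len <- sqrt(rowSums(direct^2))
  ang <- function(i, j) {
    c0 <- sum(direct[i, ] * direct[j, ]) / (len[i] * len[j])
    acos(pmin(1, pmax(-1, c0))) * 180 / pi
  }
  UnitCell(len[1], len[2], len[3], ang(2, 3), ang(1, 3), ang(1, 2))
}
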