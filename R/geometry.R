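## Exact 3D primitives used by every angle measurement in the package.
## All coordinates are numeric xyz vectors (or n x 3 matrices) in Angstrom.

# distance below which two points are treated as coincident; far below the
# 1e-3 A coordinate precision of PDB files
.COINCIDENCE_TOL <- 1e-6

.as_coord <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop(what, " must be a finite xyz vector of length 3", call. = FALSE)
  p
}

#' Backbone dihedral angle of four points
#'
#' Computes the torsion angle defined by four atoms in measurement order,
#' using the numerically stable atan2 form.  The sign follows the IUPAC
#' biochemical convention (right-handed; trans = 180 degrees), the convention
#' under which beta-strand psi angles are positive (around +140 degrees).
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors (length 3, Angstrom), in
#'   measurement order.  For phi(i) these are C(i-1), N(i), CA(i), C(i);
#'   for psi(i) they are N(i), CA(i), C(i), N(i+1).
#' @return Angle in degrees in the interval (-180, 180].
#' @details Consecutive coincident points (distance below 1e-6 Angstrom) and
#'   a collinear central triplet are degenerate geometries and raise an
#'   error rather than returning a silent 0.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # 180 (trans)
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))  # 0 (cis)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- .as_coord(p1); p2 <- .as_coord(p2); p3 <- .as_coord(p3); p4 <- .as_coord(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) <= .COINCIDENCE_TOL ||
      sqrt(sum(b2^2)) <= .COINCIDENCE_TOL ||
      sqrt(sum(b3^2)) <= .COINCIDENCE_TOL)
    stop("degenerate dihedral: consecutive points coincide", call. = FALSE)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) <= .COINCIDENCE_TOL * sqrt(sum(b1^2)) * sqrt(sum(b2^2)) ||
      sqrt(sum(n2^2)) <= .COINCIDENCE_TOL * sqrt(sum(b2^2)) * sqrt(sum(b3^2)))
    stop("degenerate dihedral: central three points are collinear", call. = FALSE)
  b2u <- b2 / sqrt(sum(b2^2))
  # atan2 form: y = (n1 x n2) . b2_hat, x = n1 . n2
  ang <- atan2(sum(.cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  wrap180(ang)
}

#' Planar angle at a vertex
#'
#' Angle a-b-c at vertex b, in degrees in [0, 180].
#'
#' @param a,b,c Numeric xyz vectors (length 3, Angstrom).
#' @return Angle in degrees.
#' @export
planar_angle <- function(a, b, c) {
  a <- .as_coord(a); b <- .as_coord(b); c <- .as_coord(c)
  v1 <- a - b
  v2 <- c - b
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 <= .COINCIDENCE_TOL || n2 <= .COINCIDENCE_TOL)
    stop("degenerate planar angle: coincident points", call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of coordinate set `b` onto `a` with a proper
#' rotation (determinant +1) and translation, returning the residual RMSD.
#' This is the metric underlying RMSD-threshold clustering of torso
#' fragments and decoy models.
#'
#' @param a,b Numeric n x 3 matrices (n >= 3) of corresponding points.
#' @return A list with `rmsd` (Angstrom), `rotation` (3 x 3 proper rotation
#'   applied to centered `b`), `translation` (length-3; full transform is
#'   `b %*% t(rotation)` after centering, then shifted onto `a`'s centroid),
#'   and `bfit`, the transformed copy of `b`.
#' @export
superpose <- function(a, b) {
  a <- .as_coord_matrix(a); b <- .as_coord_matrix(b)
  if (nrow(a) != nrow(b))
    stop("coordinate sets differ in length (", nrow(a), " vs ", nrow(b), ")",
         call. = FALSE)
  if (nrow(a) < 3L)
    stop("superposition needs at least 3 points", call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  h <- crossprod(b0, a0)            # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  bfit <- b0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((a0 - bfit)^2)))
  list(rmsd = rmsd, rotation = rot, translation = ca,
       bfit = sweep(bfit, 2L, ca, `+`))
}

#' Superposition RMSD
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom after optimal rigid superposition.
#' @export
superpose_rmsd <- function(a, b) superpose(a, b)$rmsd

#' RMSD without superposition
#'
#' Plain coordinate RMSD between two already-aligned sets; used for loop
#' RMSD after a framework fit.
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- .as_coord_matrix(a); b <- .as_coord_matrix(b)
  if (nrow(a) != nrow(b))
    stop("coordinate sets differ in length", call. = FALSE)
  sqrt(mean(rowSums((a - b)^2)))
}

.as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L || any(!is.finite(x)))
    stop("expected a finite n x 3 coordinate matrix", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Wrap an angle to (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Angles wrapped into (-180, 180].
#' @export
wrap180 <- function(x) x - 360 * ceiling((x - 180) / 360)

# radian counterpart, (-pi, pi]
wrap_pi <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))
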