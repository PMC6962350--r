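# Vector and rigid-body geometry primitives shared by every structural stage.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unit3 <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Torsion (dihedral) angle of four points
#'
#' Returns the dihedral angle defined by points `p1-p2-p3-p4` in degrees on
#' `(-180, 180]`, IUPAC sign convention (clockwise positive when viewed from
#' `p2` toward `p3`).  This is the convention used by Ramachandran plots.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Cartesian coordinates, any unit).
#' @return angle in degrees on `(-180, 180]`.
#' @export
#' @examples
#' # trans (omega = 180) arrangement:
#' dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

# Normalize an angle in degrees to (-180, 180]; -180 maps to +180.
wrap_angle <- function(a) {
  a <- ((a + 180) %% 360) - 180
  ifelse(a <= -180 + 1e-12 & a > -180 - 1e-12, 180, a)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms `a`, `b`, `c`, returns the position of
#' a fourth atom `d` with bond length `|c-d| = bond`, bond angle
#' `angle(b, c, d) = angle` and torsion `dihedral(a, b, c, d) = torsion`.
#'
#' @param a,b,c numeric 3-vectors.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param torsion dihedral angle in degrees (IUPAC convention).
#' @return numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` point sets of equal size.
#'
#' @param mobile,reference numeric matrices, n x 3, n >= 3, not collinear.
#' @return object of class `superposition` with elements `rotation` (3x3,
#'   determinant +1), `translation` (length-3), and `rmsd` (Angstrom, after
#'   applying the transform).  Apply with [apply_transform()]:
#'   `apply_transform(mobile, fit)` approximates `reference`.
#' @export
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' superpose(p, p)$rmsd  # 0
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("point sets must have identical dimensions")
  if (nrow(mobile) < 3L)
    stop("degenerate geometry: need at least 3 points to superpose")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  sv_check <- svd(P)$d
  if (sv_check[2L] < 1e-8 * max(sv_check[1L], 1e-8))
    stop("degenerate geometry: points are (near-)collinear")
  H <- crossprod(P, Q)            # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # column convention: R %*% p ~ q
  translation <- as.numeric(cr - R %*% cm)
  moved <- sweep(mobile %*% t(R), 2L, translation, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' Apply a rigid transform to coordinates
#'
#' @param x numeric n x 3 matrix of coordinates.
#' @param fit a `superposition` object from [superpose()], or a list with
#'   `rotation` and `translation`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(x, fit) {
  x <- as.matrix(x)
  sweep(x %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: rmsd = %.4f A, det(R) = %+.6f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}
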