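# Low-level 3D geometry shared by torsion, orientation and superposition code.
# All functions accept either a single 3-vector or an n x 3 matrix per atom
# slot and are vectorized over rows.

as_mat3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else x
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a * a))

#' Dihedral angle over four points
#'
#' Signed torsion angle (IUPAC convention) defined by the four points
#' `p1-p2-p3-p4`, i.e. the rotation about the `p2-p3` axis.
#'
#' @param p1,p2,p3,p4 3-vectors or n x 3 matrices of coordinates (Angstrom).
#' @param degenerate_tol geometries whose defining normals have length below
#'   this tolerance yield `NA` (collinear atoms).
#' @return angle(s) in radians in `(-pi, pi]`; `NA` where degenerate.
#' @export
dihedral_angle <- function(p1, p2, p3, p4, degenerate_tol = 1e-9) {
  p1 <- as_mat3(p1); p2 <- as_mat3(p2); p3 <- as_mat3(p3); p4 <- as_mat3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  b2u <- b2 / pmax(row_norm(b2), .Machine$double.xmin)
  m1 <- row_cross(b2u, n1)     # so the sign follows the IUPAC convention
  x <- row_dot(n1, n2)
  y <- row_dot(m1, n2)
  ang <- atan2(y, x)
  bad <- row_norm(n1) < degenerate_tol | row_norm(n2) < degenerate_tol
  ang[bad] <- NA_real_
  # map -pi to +pi so the range is (-pi, pi]
  ang[!is.na(ang) & ang <= -pi + 1e-15] <- pi
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Planar angle at a vertex
#'
#' Angle `a-b-c` at vertex `b`, in `[0, pi]`.
#'
#' @param a,b,c 3-vectors or n x 3 matrices.
#' @param degenerate_tol arms shorter than this yield `NA`.
#' @return angle(s) in radians; `NA` where an arm degenerates.
#' @export
planar_angle <- function(a, b, c, degenerate_tol = 1e-9) {
  a <- as_mat3(a); b <- as_mat3(b); c <- as_mat3(c)
  u <- a - b
  v <- c - b
  nu <- row_norm(u)
  nv <- row_norm(v)
  cs <- row_dot(u, v) / pmax(nu * nv, .Machine$double.xmin)
  cs <- pmin(1, pmax(-1, cs))
  ang <- acos(cs)
  ang[nu < degenerate_tol | nv < degenerate_tol] <- NA_real_
  if (length(ang) == 1L) as.numeric(ang) else ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the point `d` with
#' `|d - c| = bond`, planar angle `b-c-d = angle` and dihedral
#' `a-b-c-d = torsion`.
#'
#' @param a,b,c reference 3-vectors.
#' @param bond bond length in Angstrom.
#' @param angle planar angle in radians.
#' @param torsion dihedral in radians.
#' @return 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (need not be unit length).
#' @param theta rotation angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Random rotation matrix
#'
#' Uniform random proper rotation (random unit axis, uniform angle) used by
#' invariance tests and the decoy generator.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` using singular
#' value decomposition, constrained to a proper rotation.
#'
#' @param mobile,reference n x 3 coordinate matrices, matched row-by-row,
#'   n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` superposes onto `reference`, and
#'   `rmsd` (Angstrom) of the superposed points.
#' @export
superpose_kabsch <- function(mobile, reference) {
  mobile <- as_mat3(mobile); reference <- as_mat3(reference)
  if (nrow(mobile) != nrow(reference))
    stop("superpose_kabsch: point counts differ (", nrow(mobile), " vs ",
         nrow(reference), ")")
  if (nrow(mobile) < 3L)
    stop("superpose_kabsch: need at least 3 points, got ", nrow(mobile))
  if (any(!is.finite(mobile)) || any(!is.finite(reference)))
    stop("superpose_kabsch: non-finite coordinates")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)             # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)      # maps centered mobile to centered ref
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

#' Apply a rigid-body transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(as_mat3(xyz) %*% t(rotation), 2, -translation)
}

#' Root-mean-square deviation between matched coordinate sets
#'
#' Plain coordinate RMSD without any fitting.
#'
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as_mat3(a); b <- as_mat3(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}
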