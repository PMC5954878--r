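# Rigid-body transform algebra and Euler-angle (z-y-x) conventions.
#
# A rigid transform is represented as a plain 4x4 homogeneous matrix with an
# orthonormal, proper (det = +1) rotation block, translations in mm, and
# bottom row [0, 0, 0, 1].  All angle arguments are in radians; file and CLI
# serializations use degrees.

.RIGID_TOL <- 1e-9

#' Construct (and validate) a rigid transform
#'
#' Builds a 4x4 homogeneous rigid-body transform from a rotation matrix and a
#' translation vector, or validates an existing 4x4 matrix. Translations are
#' in millimetres.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1, or a
#'   full 4x4 homogeneous matrix (in which case \code{translation} must be
#'   missing).
#' @param translation length-3 numeric translation (mm).
#' @return A validated 4x4 matrix.
#' @examples
#' rigid_transform(diag(3), c(1, 2, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (is.matrix(rotation) && all(dim(rotation) == c(4, 4))) {
    m <- rotation
  } else {
    stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
              length(translation) == 3)
    m <- rbind(cbind(rotation, as.numeric(translation)), c(0, 0, 0, 1))
  }
  if (!all(is.finite(m)))
    stop("rigid transform contains non-finite entries")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation block is not orthonormal")
  if (det(R) < 0)
    stop("rotation block is a reflection (det < 0)")
  if (any(m[4, ] != c(0, 0, 0, 1)))
    stop("bottom row of a rigid transform must be [0, 0, 0, 1]")
  dimnames(m) <- NULL
  m
}

#' Test whether a matrix is a valid rigid transform
#'
#' @param m object to test.
#' @param tol tolerance on orthonormality of the rotation block.
#' @return Logical scalar.
#' @export
is_rigid_transform <- function(m, tol = 1e-8) {
  is.matrix(m) && all(dim(m) == c(4, 4)) && all(is.finite(m)) &&
    max(abs(crossprod(m[1:3, 1:3]) - diag(3))) <= tol &&
    det(m[1:3, 1:3]) > 0 &&
    all(m[4, ] == c(0, 0, 0, 1))
}

# elementary rotations (column-vector convention)
.rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
.rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
.rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Normalize an angle to (-pi, pi]
#'
#' @param a angle(s) in radians.
#' @return Angle(s) wrapped into the half-open interval (-pi, pi].
#' @export
normalize_angle <- function(a) {
  -(((-a + pi) %% (2 * pi)) - pi)
}

#' Build a rigid transform from z-y-x Euler angles
#'
#' The rotation is composed as Rz(alpha) %*% Ry(beta) %*% Rx(gamma) acting on
#' column vectors: first a rotation about x (elevation), then y (lateral),
#' then z (axial), which is the axial-lateral-elevation sequence used to
#' parameterize the image-to-probe calibration matrix.
#'
#' @param angles length-3 numeric: alpha (about z), beta (about y), gamma
#'   (about x), in radians.
#' @param translation length-3 numeric translation (mm).
#' @return 4x4 rigid transform.
#' @examples
#' euler_zyx_to_transform(c(pi / 2, 0, 0), c(0, 0, 0))
#' @export
euler_zyx_to_transform <- function(angles, translation = c(0, 0, 0)) {
  if (length(angles) != 3 || !all(is.finite(angles)))
    stop("'angles' must be three finite values (alpha, beta, gamma)")
  if (length(translation) != 3 || !all(is.finite(translation)))
    stop("'translation' must be three finite values")
  R <- .rot_z(angles[1]) %*% .rot_y(angles[2]) %*% .rot_x(angles[3])
  rigid_transform(R, translation)
}

#' Extract z-y-x Euler angles and translation from a rigid transform
#'
#' Inverse of [euler_zyx_to_transform()]. At gimbal lock (|beta| = pi/2 the
#' alpha/gamma split is not unique) the convention gamma = 0 is used, which
#' still reconstructs the input transform exactly.
#'
#' @param m 4x4 rigid transform.
#' @return List with \code{angles} (alpha, beta, gamma in radians, each in
#'   (-pi, pi]) and \code{translation} (mm).
#' @export
transform_to_euler_zyx <- function(m) {
  if (!is_rigid_transform(m))
    stop("'m' is not a valid rigid transform")
  R <- m[1:3, 1:3]
  # R[3,1] = -sin(beta)
  sb <- -R[3, 1]
  sb <- min(1, max(-1, sb))
  beta <- asin(sb)
  if (abs(abs(sb) - 1) < 1e-12) {
    # gimbal lock: fix gamma = 0, then R = Rz(alpha) Ry(+/-pi/2)
    gamma <- 0
    alpha <- atan2(-R[1, 2], R[2, 2])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- atan2(R[3, 2], R[3, 3])
  }
  list(angles = normalize_angle(c(alpha, beta, gamma)),
       translation = m[1:3, 4])
}

#' Compose two rigid transforms
#'
#' \code{compose(A, B)} returns the transform that applies \code{B} first and
#' then \code{A} (matrix product \code{A %*% B}).
#'
#' @param a,b 4x4 rigid transforms.
#' @return 4x4 rigid transform.
#' @export
compose_transforms <- function(a, b) {
  if (!is_rigid_transform(a) || !is_rigid_transform(b))
    stop("both arguments must be valid rigid transforms")
  m <- a %*% b
  # re-orthonormalize drift from repeated composition
  m[4, ] <- c(0, 0, 0, 1)
  m
}

#' Invert a rigid transform
#'
#' Uses the closed form inv(T) = [R' | -R' t] rather than a general matrix
#' inverse.
#'
#' @param m 4x4 rigid transform.
#' @return 4x4 rigid transform such that \code{compose_transforms(m, invert_transform(m))}
#'   is the identity.
#' @export
invert_transform <- function(m) {
  if (!is_rigid_transform(m))
    stop("'m' is not a valid rigid transform")
  Rt <- t(m[1:3, 1:3])
  rbind(cbind(Rt, -Rt %*% m[1:3, 4]), c(0, 0, 0, 1))
}

#' Apply a rigid transform to 3D points
#'
#' @param m 4x4 rigid transform.
#' @param p length-3 point or n x 3 matrix of points (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(m, p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    out <- p %*% t(m[1:3, 1:3])
    out <- sweep(out, 2, m[1:3, 4], "+")
    out
  } else {
    stopifnot(length(p) == 3)
    as.numeric(m[1:3, 1:3] %*% p + m[1:3, 4])
  }
}

#' Closed-form rigid point-set registration (absolute orientation)
#'
#' Finds the rigid transform T minimizing sum_i ||dst_i - T(src_i)||^2 by the
#' SVD method with determinant-sign correction, so the solution is always a
#' proper rotation even for coplanar point sets.
#'
#' @param src n x 3 matrix of source points (n >= 3, non-collinear).
#' @param dst n x 3 matrix of corresponding destination points.
#' @return 4x4 rigid transform mapping \code{src} onto \code{dst} in the
#'   least-squares sense.
#' @export
fit_rigid <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (!is.numeric(src) || !is.numeric(dst) || ncol(src) != 3 || ncol(dst) != 3)
    stop("'src' and 'dst' must be n x 3 numeric matrices")
  n <- nrow(src)
  if (nrow(dst) != n)
    stop("'src' and 'dst' must contain the same number of points")
  if (n < 3)
    stop("degenerate configuration: at least 3 point pairs are required")
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
  # collinear sources leave the rotation about the line undetermined
  sv_x <- svd(X, nu = 0, nv = 0)$d
  if (sv_x[2] < 1e-9 * max(sv_x[1], 1))
    stop("degenerate configuration: source points are collinear")
  H <- crossprod(X, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  # polish orthonormality against accumulated roundoff
  ps <- svd(R)
  R <- ps$u %*% t(ps$v)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Serialize a transform to a row-major length-16 vector
#'
#' @param m 4x4 matrix.
#' @return Numeric vector of length 16 (row-major order).
#' @export
transform_to_row_major <- function(m) {
  as.numeric(t(m))
}

#' Rebuild a transform from a row-major length-16 vector
#'
#' @param v numeric vector of length 16, row-major.
#' @param validate validate rigid-transform invariants (default TRUE).
#' @return 4x4 matrix.
#' @export
transform_from_row_major <- function(v, validate = TRUE) {
  stopifnot(length(v) == 16)
  m <- matrix(as.numeric(v), 4, 4, byrow = TRUE)
  if (validate) rigid_transform(m) else m
}
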