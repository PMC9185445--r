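# SE(3) twist parametrisation and rigid-transform utilities.
#
# A twist is a 6-vector xi = (w1, w2, w3, v1, v2, v3): the first three
# components generate an infinitesimal rotation (axis-angle, radians), the
# last three an infinitesimal translation. The exponential map sends a twist
# to a 4x4 homogeneous rigid transform.

#' Skew-symmetric (hat) matrix of a 3-vector
#' @param w Numeric length-3 vector.
#' @return 3x3 skew-symmetric matrix.
#' @keywords internal
skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), nrow = 3L)
}

#' Exponential map from a twist to a rigid transform
#'
#' Maps a 6-parameter twist (3 rotation, 3 translation) to its SE(3) element
#' as a 4x4 homogeneous matrix, using the closed-form Rodrigues expression
#' with a Taylor-series fallback for angles near zero.
#'
#' @param xi Numeric length-6 twist: rotation components first (radians),
#'   then translation components.
#' @return A 4x4 homogeneous rigid-transform matrix (rotation block
#'   orthonormal with unit determinant, bottom row `(0, 0, 0, 1)`).
#' @examples
#' se3_exp(c(0, 0, pi / 2, 0, 0, 0))  # 90 degree rotation about z
#' @export
se3_exp <- function(xi) {
  xi <- as.numeric(xi)
  if (length(xi) != 6L) stop("twist must have exactly 6 components", call. = FALSE)
  if (!all(is.finite(xi))) stop("twist components must be finite", call. = FALSE)
  w <- xi[1:3]
  v <- xi[4:6]
  theta <- sqrt(sum(w^2))
  K <- skew3(w)
  K2 <- K %*% K
  if (theta < 1e-8) {
    # series: sin(t)/t ~ 1 - t^2/6, (1-cos t)/t^2 ~ 1/2 - t^2/24,
    #         (t - sin t)/t^3 ~ 1/6 - t^2/120
    A <- 1 - theta^2 / 6
    B <- 0.5 - theta^2 / 24
    C <- 1 / 6 - theta^2 / 120
  } else {
    A <- sin(theta) / theta
    B <- (1 - cos(theta)) / theta^2
    C <- (theta - sin(theta)) / theta^3
  }
  R <- diag(3) + A * K + B * K2
  V <- diag(3) + B * K + C * K2
  G <- diag(4)
  G[1:3, 1:3] <- R
  G[1:3, 4] <- V %*% v
  G
}

#' Validate a rigid transform
#'
#' @param G 4x4 matrix.
#' @param tol Orthonormality tolerance on the rotation block.
#' @return Logical scalar.
#' @export
is_rigid_transform <- function(G, tol = 1e-8) {
  if (!is.matrix(G) || !all(dim(G) == c(4L, 4L))) return(FALSE)
  if (!all(G[4, ] == c(0, 0, 0, 1))) return(FALSE)
  R <- G[1:3, 1:3]
  ortho <- norm(crossprod(R) - diag(3), type = "F")
  ortho < tol && det(R) > 0
}

#' Invert a rigid transform
#' @param G 4x4 rigid transform.
#' @return The inverse transform, also rigid.
#' @export
rigid_inverse <- function(G) {
  R <- G[1:3, 1:3]
  t <- G[1:3, 4]
  Gi <- diag(4)
  Gi[1:3, 1:3] <- t(R)
  Gi[1:3, 4] <- -t(R) %*% t
  Gi
}

#' Apply a rigid transform to a point cloud
#' @param G 4x4 rigid transform.
#' @param points N x 3 coordinate matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(G, points) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  out <- points %*% t(G[1:3, 1:3])
  out <- sweep(out, 2L, G[1:3, 4], "+")
  dimnames(out) <- dimnames(points)
  out
}

#' Rotation matrix from axis and angle
#' @param axis Length-3 axis (normalised internally).
#' @param angle Rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(diag(3))
  se3_exp(c(axis / n * angle, 0, 0, 0))[1:3, 1:3]
}

#' Registration loss between an estimate and the ground truth
#'
#' Frobenius norm of `solve(estimate) %*% ground_truth - I4`: zero exactly
#' when the estimate recovers the ground-truth transform, and invariant to
#' left-composition of both arguments by a common rigid motion.
#'
#' @param estimate,ground_truth 4x4 rigid transforms.
#' @return Nonnegative scalar loss.
#' @export
registration_loss <- function(estimate, ground_truth) {
  stopifnot(is_rigid_transform(estimate, tol = 1e-6),
            is_rigid_transform(ground_truth, tol = 1e-6))
  norm(rigid_inverse(estimate) %*% ground_truth - diag(4), type = "F")
}

#' Angular difference between the rotation blocks of two transforms
#' @param G1,G2 4x4 rigid transforms.
#' @return Rotation geodesic distance in degrees.
#' @export
rotation_error_deg <- function(G1, G2) {
  R <- G1[1:3, 1:3] %*% t(G2[1:3, 1:3])
  c <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c))) * 180 / pi
}

#' Euclidean difference between the translation parts of two transforms
#' @param G1,G2 4x4 rigid transforms.
#' @return Nonnegative scalar.
#' @export
translation_error <- function(G1, G2) {
  sqrt(sum((G1[1:3, 4] - G2[1:3, 4])^2))
}

#' Closed-form rigid alignment with known correspondences (Kabsch)
#'
#' Least-squares rigid transform mapping `source` onto `target` when row i
#' of the two clouds correspond, via the singular value decomposition of the
#' cross-covariance (reflections excluded). Serves as the correspondence-
#' based oracle against which feature-space registration is validated.
#'
#' @param source,target N x 3 matrices with row-wise correspondence.
#' @return 4x4 rigid transform `G` with `apply_transform(G, source)` closest
#'   to `target` in least squares.
#' @export
kabsch_align <- function(source, target) {
  stopifnot(is.matrix(source), is.matrix(target),
            all(dim(source) == dim(target)), ncol(source) == 3L)
  ps <- colMeans(source)
  pt <- colMeans(target)
  H <- crossprod(sweep(source, 2L, ps), sweep(target, 2L, pt))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  G <- diag(4)
  G[1:3, 1:3] <- R
  G[1:3, 4] <- pt - R %*% ps
  G
}
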