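#' Muscle stiffnesses for a given activation
#'
#' Active musculotendon stiffness is taken linear in muscle force: muscle `i`
#' at activation `a[i]` produces force `f_max[i] * a[i]` and stiffness
#' `alpha * f_max[i] * a[i]` (a lumped-parameter model of the active
#' musculotendon unit).
#'
#' @param arm an [arm_model()].
#' @param a numeric activation vector, one entry per muscle, each in `[0, 1]`.
#' @return Numeric vector of muscle stiffnesses (the diagonal of the muscle
#'   stiffness matrix).
#' @export
muscle_stiffness <- function(arm, a) {
  a <- check_activation(arm, a)
  arm$alpha * arm$f_max * a
}

check_activation <- function(arm, a, tol = 1e-9) {
  a <- as.numeric(a)
  if (length(a) != arm$n_muscles)
    stop("activation must have ", arm$n_muscles, " entries")
  if (any(!is.finite(a)) || any(a < -tol) || any(a > 1 + tol))
    stop("activations must lie in [0, 1]")
  pmin(1, pmax(0, a))
}

#' Joint stiffness matrix
#'
#' `K_joint = R %*% diag(k) %*% t(R)` where `k` are the muscle stiffnesses:
#' the sum over muscles of `k_i * rho_i %*% t(rho_i)` with `rho_i` the
#' moment-arm column of muscle `i`. Symmetric and positive semidefinite for
#' any nonnegative activation.
#'
#' @inheritParams muscle_stiffness
#' @return A joints x joints numeric matrix.
#' @export
joint_stiffness <- function(arm, a) {
  k <- muscle_stiffness(arm, a)
  R <- arm$moment_arms
  K <- R %*% (k * t(R))
  (K + t(K)) / 2
}

#' Endpoint stiffness matrix
#'
#' Congruence transform of the joint stiffness by the inverse Jacobian (the
#' zero-external-force form): `K_end = t(solve(J)) %*% K_joint %*% solve(J)`.
#'
#' @inheritParams muscle_stiffness
#' @param theta joint angles (radians); the Jacobian must be invertible
#'   there.
#' @return A symmetric 2 x 2 numeric matrix.
#' @export
endpoint_stiffness <- function(arm, theta, a) {
  Ji <- jacobian_inverse(arm, theta)
  K <- t(Ji) %*% joint_stiffness(arm, a) %*% Ji
  (K + t(K)) / 2
}

#' Linear map from activations to the vectorized endpoint stiffness
#'
#' Because endpoint stiffness is linear in the activation vector, the three
#' independent entries of the symmetric endpoint stiffness matrix can be
#' written as `M %*% a` for a fixed 3 x M matrix `M` that depends only on
#' the arm and the posture. Row order is `(K_xx, K_xy, K_yy)`. Column `i` is
#' the vectorized rank-one stiffness contribution of muscle `i` at full
#' activation: with `u_i = t(solve(J)) %*% rho_i`,
#' `M[, i] = alpha * f_max[i] * (u_i[1]^2, u_i[1] u_i[2], u_i[2]^2)`.
#'
#' These three linear equations (plus the two torque-equilibrium equations)
#' are the equality constraints of the stiffness-realizability problem.
#'
#' @inheritParams endpoint_stiffness
#' @return A 3 x M numeric matrix.
#' @seealso [task_constraints()], [endpoint_stiffness()]
#' @export
stiffness_linear_map <- function(arm, theta) {
  Ji <- jacobian_inverse(arm, theta)
  U <- t(Ji) %*% arm$moment_arms          # columns u_i
  M <- rbind(U[1, ]^2, U[1, ] * U[2, ], U[2, ]^2)
  M * rep(arm$alpha * arm$f_max, each = 3)
}

# (kxx, kxy, kyy) <-> symmetric 2x2
vec_to_sym <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
sym_to_vec <- function(K) c(K[1, 1], (K[1, 2] + K[2, 1]) / 2, K[2, 2])

#' Summarize a stiffness matrix as an ellipse
#'
#' Eigendecomposition of a symmetric positive-definite 2 x 2 stiffness
#' matrix, reported as the ellipse summary used throughout the package:
#' `size` (trace), `shape` (condition number, major/minor eigenvalue, >= 1),
#' and `orientation` (angle of the major axis from the x-axis, degrees in
#' `[0, 180)`). For an isotropic matrix the orientation is undefined and
#' returned as `NA` with `orientation_defined = FALSE`. `area` (pi times the
#' geometric mean of the eigenvalues squared rooted, i.e.
#' `pi * sqrt(l1 * l2)`) is included as an alternative size measure.
#'
#' @param K symmetric positive-definite 2 x 2 matrix (or a 3-vector
#'   `(kxx, kxy, kyy)`).
#' @param tol eigenvalue-gap tolerance below which the matrix is treated as
#'   isotropic.
#' @return An object of class `stiffness_ellipse`: list with `size`, `area`,
#'   `shape`, `orientation` (degrees), `orientation_defined`, `eigenvalues`.
#' @examples
#' stiffness_ellipse(diag(c(4, 1)))  # shape 4, orientation 0
#' @export
stiffness_ellipse <- function(K, tol = 1e-9) {
  if (is.numeric(K) && is.null(dim(K)) && length(K) == 3) K <- vec_to_sym(K)
  if (!is.matrix(K) || any(dim(K) != 2))
    stop("K must be a 2 x 2 matrix or a (kxx, kxy, kyy) 3-vector")
  if (max(abs(K - t(K))) > 1e-8 * (1 + max(abs(K))))
    stop("K must be symmetric")
  if (max(abs(K)) == 0) stop("zero matrix has no ellipse")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lmax <- e$values[1]; lmin <- e$values[2]
  if (lmin <= 0)
    stop("K is not positive definite (min eigenvalue ", signif(lmin, 4),
         "); not an ellipse")
  defined <- (lmax - lmin) > tol * lmax
  orientation <- NA_real_
  if (defined) {
    v <- e$vectors[, 1]
    orientation <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  }
  structure(list(size = lmax + lmin,
                 area = pi * sqrt(lmax * lmin),
                 shape = lmax / lmin,
                 orientation = orientation,
                 orientation_defined = defined,
                 eigenvalues = c(lmax, lmin)),
            class = "stiffness_ellipse")
}

#' @export
print.stiffness_ellipse <- function(x, ...) {
  cat(sprintf("<stiffness_ellipse> size (trace) %.4g, shape (cond) %.4g, orientation %s\n",
              x$size, x$shape,
              if (x$orientation_defined)
                sprintf("%.2f deg", x$orientation) else "undefined (isotropic)"))
  invisible(x)
}

#' Desired endpoint stiffness from ellipse parameters
#'
#' Builds the vectorized symmetric stiffness matrix whose ellipse has the
#' given condition number, major-axis orientation, and scale:
#' `scale * Rot(phi) %*% diag(shape, 1) %*% t(Rot(phi))`. Round-trips through
#' [stiffness_ellipse()].
#'
#' @param shape condition number, >= 1.
#' @param orientation_deg major-axis angle in degrees.
#' @param scale positive scalar multiplying the whole matrix (the minor
#'   eigenvalue equals `scale`).
#' @return Numeric 3-vector `(kxx, kxy, kyy)`.
#' @export
desired_stiffness <- function(shape, orientation_deg, scale = 1) {
  if (!is.numeric(shape) || shape < 1) stop("shape must be >= 1")
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  phi <- orientation_deg * pi / 180
  cp <- cos(phi); sp <- sin(phi)
  Rot <- matrix(c(cp, sp, -sp, cp), 2, 2)
  sym_to_vec(scale * Rot %*% diag(c(shape, 1)) %*% t(Rot))
}
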