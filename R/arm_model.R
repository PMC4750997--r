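#' Construct a planar tendon-driven arm model
#'
#' An arm model bundles the geometry and muscle routing of a planar limb:
#' link lengths, the signed moment-arm matrix `R` (joints x muscles, so that
#' joint torque is `tau = R %*% F` for a vector of muscle forces), maximal
#' muscle forces, the muscle stiffness-per-force scale `alpha`, and joint
#' limits. All quantities are dimensionless model units; angles are radians.
#'
#' The sign convention is that a positive moment arm produces flexor torque.
#' Every muscle must act on at least one joint (no zero columns in
#' `moment_arms`).
#'
#' @param link_lengths positive numeric vector of link lengths, one per link
#'   (two for the planar two-link arm, one for a single-joint limb).
#' @param moment_arms numeric matrix, joints x muscles, signed moment arms.
#' @param f_max positive numeric vector of maximal muscle forces (recycled to
#'   the number of muscles if scalar).
#' @param alpha positive scalar: muscle stiffness per unit muscle force.
#' @param joint_limits numeric matrix, joints x 2, `[min, max]` joint angles
#'   in radians.
#' @param muscle_names optional character vector of muscle labels.
#'
#' @return An object of class `arm_model`: a list with the validated fields
#'   plus `n_joints` and `n_muscles`.
#' @seealso [default_arm()], [single_joint_arm()], [forward_kinematics()]
#' @export
arm_model <- function(link_lengths, moment_arms, f_max = 1, alpha = 1,
                      joint_limits = NULL, muscle_names = NULL) {
  moment_arms <- as.matrix(moment_arms)
  n_joints <- nrow(moment_arms)
  n_muscles <- ncol(moment_arms)
  link_lengths <- as.numeric(link_lengths)
  if (length(link_lengths) != n_joints)
    stop("need one link length per joint (", n_joints, "), got ",
         length(link_lengths))
  if (any(!is.finite(link_lengths)) || any(link_lengths <= 0))
    stop("link_lengths must be positive and finite")
  if (any(!is.finite(moment_arms)))
    stop("moment_arms must be finite")
  if (any(colSums(abs(moment_arms)) == 0))
    stop("every muscle must have a nonzero moment arm about some joint")
  f_max <- rep_len(as.numeric(f_max), n_muscles)
  if (any(!is.finite(f_max)) || any(f_max <= 0))
    stop("f_max must be positive and finite")
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a positive scalar")
  if (is.null(joint_limits)) {
    joint_limits <- default_joint_limits(n_joints)
  }
  joint_limits <- matrix(as.numeric(joint_limits), ncol = 2)
  if (nrow(joint_limits) != n_joints)
    stop("joint_limits must be a ", n_joints, " x 2 matrix")
  if (any(joint_limits[, 1] >= joint_limits[, 2]))
    stop("each joint limit row must satisfy min < max")
  if (is.null(muscle_names))
    muscle_names <- paste0("m", seq_len(n_muscles))
  structure(
    list(link_lengths = link_lengths, moment_arms = moment_arms,
         f_max = f_max, alpha = alpha, joint_limits = joint_limits,
         muscle_names = muscle_names,
         n_joints = n_joints, n_muscles = n_muscles),
    class = "arm_model")
}

# Default workspace: shoulder in [0, 160] deg, elbow in [5, 175] deg.
# A plausible human planar workspace that keeps the elbow away from the
# Jacobian singularities at 0 and 180 degrees.
default_joint_limits <- function(n_joints) {
  if (n_joints == 2) {
    rbind(c(0, 160), c(5, 175)) * pi / 180
  } else {
    matrix(rep(c(-pi / 2, pi / 2), each = n_joints), ncol = 2)
  }
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model>: ", x$n_joints, " joint(s), ", x$n_muscles,
      " muscles\n", sep = "")
  cat("  link lengths:", paste(signif(x$link_lengths, 4), collapse = ", "),
      "\n")
  cat("  alpha:", x$alpha, " f_max:",
      paste(signif(x$f_max, 4), collapse = ", "), "\n")
  cat("  moment arms (joints x muscles):\n")
  m <- x$moment_arms
  dimnames(m) <- list(paste0("j", seq_len(nrow(m))), x$muscle_names)
  print(m)
  invisible(x)
}

stopifnot_two_link <- function(arm) {
  if (arm$n_joints != 2)
    stop("this operation requires a two-link planar arm (n_joints = 2)")
}

check_theta <- function(arm, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != arm$n_joints || any(!is.finite(theta)))
    stop("theta must be ", arm$n_joints, " finite joint angles (radians)")
  theta
}

#' Forward kinematics of the planar two-link arm
#'
#' @param arm an [arm_model()] with two joints.
#' @param theta numeric vector of 2 joint angles (radians): shoulder, elbow.
#' @return Endpoint position as a numeric 2-vector `(x, y)`.
#' @examples
#' arm <- default_arm()
#' forward_kinematics(arm, c(pi / 6, 2 * pi / 3))  # (0, 1)
#' @export
forward_kinematics <- function(arm, theta) {
  stopifnot_two_link(arm)
  theta <- check_theta(arm, theta)
  l <- arm$link_lengths
  c(l[1] * cos(theta[1]) + l[2] * cos(theta[1] + theta[2]),
    l[1] * sin(theta[1]) + l[2] * sin(theta[1] + theta[2]))
}

#' Inverse kinematics of the planar two-link arm
#'
#' Places the endpoint at a target position; the elbow branch selects the
#' sign of the elbow angle.
#'
#' @param arm an [arm_model()] with two joints.
#' @param endpoint numeric 2-vector, target endpoint position.
#' @param branch `"elbow_positive"` (elbow angle in `[0, pi]`) or
#'   `"elbow_negative"`.
#' @return Joint angles (radians) such that [forward_kinematics()] reproduces
#'   `endpoint`.
#' @export
inverse_kinematics <- function(arm, endpoint,
                               branch = c("elbow_positive",
                                          "elbow_negative")) {
  stopifnot_two_link(arm)
  branch <- match.arg(branch)
  endpoint <- as.numeric(endpoint)
  if (length(endpoint) != 2 || any(!is.finite(endpoint)))
    stop("endpoint must be a finite 2-vector")
  l <- arm$link_lengths
  r <- sqrt(sum(endpoint^2))
  r_min <- abs(l[1] - l[2])
  r_max <- l[1] + l[2]
  if (r < r_min - 1e-12 || r > r_max + 1e-12)
    stop(sprintf(
      "endpoint at distance %.6g is unreachable: reachable annulus is [%.6g, %.6g]",
      r, r_min, r_max))
  cos_t2 <- (r^2 - l[1]^2 - l[2]^2) / (2 * l[1] * l[2])
  cos_t2 <- min(1, max(-1, cos_t2))
  t2 <- acos(cos_t2)
  if (branch == "elbow_negative") t2 <- -t2
  t1 <- atan2(endpoint[2], endpoint[1]) -
    atan2(l[2] * sin(t2), l[1] + l[2] * cos(t2))
  c(t1, t2)
}

#' Manipulator Jacobian of the planar two-link arm
#'
#' Columns are the partial derivatives of the endpoint position with respect
#' to the shoulder and elbow angles. The Jacobian is singular iff
#' `sin(theta[2]) == 0` (full extension or full fold); its determinant is
#' `l1 * l2 * sin(theta2)`.
#'
#' @inheritParams forward_kinematics
#' @return A 2 x 2 numeric matrix.
#' @export
arm_jacobian <- function(arm, theta) {
  stopifnot_two_link(arm)
  theta <- check_theta(arm, theta)
  l <- arm$link_lengths
  s1 <- sin(theta[1]); c1 <- cos(theta[1])
  s12 <- sin(theta[1] + theta[2]); c12 <- cos(theta[1] + theta[2])
  matrix(c(-l[1] * s1 - l[2] * s12, l[1] * c1 + l[2] * c12,
           -l[2] * s12, l[2] * c12), 2, 2)
}

# Inverse Jacobian with an informative singularity error.
jacobian_inverse <- function(arm, theta) {
  J <- arm_jacobian(arm, theta)
  if (abs(sin(theta[2])) < 1e-10)
    stop(sprintf(
      "singular Jacobian: elbow angle theta2 = %.6g rad is a multiple of pi",
      theta[2]))
  solve(J)
}

#' Uniform grid of non-singular postures over the joint limits
#'
#' Lays an `n1 x n2` grid of joint angles uniformly over the arm's joint
#' limits and drops postures whose Jacobian is (near-)singular.
#'
#' @param arm an [arm_model()] with two joints.
#' @param n1,n2 grid counts per joint (each at least 2).
#' @param singular_tol postures with `abs(sin(theta2))` below this are
#'   dropped.
#' @return A matrix with columns `theta1`, `theta2` (radians), one row per
#'   retained posture; the number of dropped postures is in attribute
#'   `"n_dropped"`.
#' @export
posture_grid <- function(arm, n1, n2, singular_tol = 1e-6) {
  stopifnot_two_link(arm)
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be at least 2")
  lim <- arm$joint_limits
  g <- expand.grid(theta1 = seq(lim[1, 1], lim[1, 2], length.out = n1),
                   theta2 = seq(lim[2, 1], lim[2, 2], length.out = n2))
  keep <- abs(sin(g$theta2)) >= singular_tol
  out <- as.matrix(g[keep, , drop = FALSE])
  if (nrow(out) == 0)
    stop("no non-singular postures remain after filtering the grid")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
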