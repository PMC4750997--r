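#' The nominal 6-muscle planar arm
#'
#' Two unit-length links, six muscles with unit moment-arm magnitudes,
#' `f_max = 1` for every muscle, `alpha = 1`. Muscle order (fixed throughout
#' the package): shoulder flexor, shoulder extensor, elbow flexor, elbow
#' extensor, bi-articular flexor, bi-articular extensor. Positive moment arm
#' means flexor torque; the bi-articular muscles act with the same sign on
#' both joints (no cross-over bi-articulars).
#'
#' @param joint_limits optional joints x 2 limits in radians; default
#'   shoulder `[0, 160]` degrees, elbow `[5, 175]` degrees.
#' @return An [arm_model()].
#' @export
default_arm <- function(joint_limits = NULL) {
  R <- cbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1))
  arm_model(link_lengths = c(1, 1), moment_arms = R, f_max = 1, alpha = 1,
            joint_limits = joint_limits,
            muscle_names = c("sh_flex", "sh_ext", "el_flex", "el_ext",
                             "bi_flex", "bi_ext"))
}

#' A single-joint, three-muscle limb
#'
#' The minimal system in which the stiffness-realizability geometry is fully
#' visualizable: one rotational joint, three muscles, so the equality
#' constraints are one torque row and one joint-stiffness row and the
#' feasible activation set is a segment in the 3-cube.
#'
#' @param moment_arms signed 3-vector of moment arms (default `c(1, 2, -1)`).
#'   A warning is issued if all moment arms share one sign, since torque
#'   equilibrium then forces zero activation and no positive stiffness is
#'   realizable.
#' @param f_max,alpha as in [arm_model()].
#' @return An [arm_model()] with one joint.
#' @export
single_joint_arm <- function(moment_arms = c(1, 2, -1), f_max = 1,
                             alpha = 1) {
  moment_arms <- as.numeric(moment_arms)
  if (length(moment_arms) != 3 || any(moment_arms == 0))
    stop("moment_arms must be 3 nonzero values")
  if (all(moment_arms > 0) || all(moment_arms < 0))
    warning("all moment arms share one sign: equilibrium forces zero ",
            "activation and positive stiffness is unrealizable")
  arm_model(link_lengths = 1, moment_arms = matrix(moment_arms, 1, 3),
            f_max = f_max, alpha = alpha,
            joint_limits = matrix(c(-pi / 2, pi / 2), 1, 2))
}

#' A reproducible random arm model for property testing
#'
#' Draws a two-link (or one-link) arm with random moment-arm magnitudes
#' uniform in `[0.3, 1.5]` (bounded away from zero to avoid near-singular
#' systems) and sign patterns guaranteeing each joint has both a flexor and
#' an extensor, so a strictly positive equilibrium activation exists and the
#' moment-arm matrix has full row rank. Deterministic for a fixed seed.
#'
#' @param n_muscles number of muscles (at least `n_joints + 1`).
#' @param n_joints 1 or 2.
#' @param seed integer seed.
#' @param range magnitude range for moment arms.
#' @return An [arm_model()].
#' @export
random_arm <- function(n_muscles = 6, n_joints = 2, seed = 1,
                       range = c(0.3, 1.5)) {
  if (n_muscles < n_joints + 1)
    stop("need more muscles than joints for an equilibrium-capable arm")
  withr_seed(seed, {
    for (attempt in 1:500) {
      R <- matrix(0, n_joints, n_muscles)
      for (i in seq_len(n_muscles)) {
        joints <- which(stats::runif(n_joints) < 0.75)
        if (length(joints) == 0) joints <- sample.int(n_joints, 1)
        R[joints, i] <- sample(c(-1, 1), length(joints), replace = TRUE) *
          stats::runif(length(joints), range[1], range[2])
      }
      # antagonist coverage: each joint needs a flexor and an extensor
      if (!all(apply(R, 1, function(r) any(r > 0) && any(r < 0)))) next
      if (qr(R)$rank != n_joints) next
      f_max <- stats::runif(n_muscles, 0.5, 1.5)
      # strictly interior equilibrium-capable activation: a positive
      # activation with zero net torque must exist
      a_int <- polytope_feasible_point(R %*% diag(f_max),
                                       rep(0, n_joints),
                                       lower = rep(0.05, n_muscles),
                                       upper = rep(0.95, n_muscles))
      if (is.null(a_int)) next
      ll <- stats::runif(n_joints, 0.7, 1.3)
      return(arm_model(link_lengths = ll, moment_arms = R, f_max = f_max,
                       alpha = 1))
    }
    stop("failed to draw a well-conditioned random arm in 500 attempts")
  })
}

#' A random non-singular posture within the joint limits
#'
#' @param arm an [arm_model()] with two joints.
#' @param seed integer seed.
#' @param singular_tol minimum `abs(sin(theta2))`.
#' @return Joint angles (radians).
#' @export
random_posture <- function(arm, seed = 1, singular_tol = 1e-3) {
  withr_seed(seed, {
    for (attempt in 1:100) {
      th <- stats::runif(arm$n_joints, arm$joint_limits[, 1],
                         arm$joint_limits[, 2])
      if (arm$n_joints < 2 || abs(sin(th[2])) >= singular_tol)
        return(th)
    }
    stop("could not draw a non-singular posture")
  })
}
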