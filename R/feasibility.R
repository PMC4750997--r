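#' Assemble the equality constraints of a stiffness task
#'
#' Stacks the torque-equilibrium rows (`R %*% diag(f_max) %*% a = 0`, one row
#' per joint) and the stiffness rows (linear activation-to-stiffness map
#' equal to the desired vectorized stiffness). For the two-link arm the
#' stiffness block is the 3 x M endpoint-stiffness map at the given posture;
#' for a single-joint limb it is the 1 x M joint-stiffness row, and `theta`
#' is ignored.
#'
#' @param arm an [arm_model()].
#' @param theta joint angles (radians); required for two-joint arms.
#' @param desired desired vectorized stiffness: length 3 `(kxx, kxy, kyy)`
#'   for a two-joint arm, length 1 (joint stiffness) for a single-joint limb.
#' @return An object of class `task_constraints`: list with `A_eq`, `b_eq`,
#'   `lower`, `upper`, `f_max`, `arm`.
#' @export
task_constraints <- function(arm, theta = NULL, desired) {
  desired <- as.numeric(desired)
  torque_rows <- arm$moment_arms %*% diag(arm$f_max, arm$n_muscles)
  if (arm$n_joints == 2) {
    if (length(desired) != 3)
      stop("desired must be (kxx, kxy, kyy) for a two-joint arm")
    if (is.null(theta)) stop("theta is required for a two-joint arm")
    stiff_rows <- stiffness_linear_map(arm, theta)
  } else if (arm$n_joints == 1) {
    if (length(desired) != 1)
      stop("desired must be a single joint stiffness for a one-joint limb")
    stiff_rows <- matrix(arm$alpha * arm$f_max * arm$moment_arms[1, ]^2,
                         nrow = 1)
  } else {
    stop("only one- and two-joint models are supported")
  }
  structure(list(A_eq = rbind(torque_rows, stiff_rows),
                 b_eq = c(rep(0, arm$n_joints), desired),
                 lower = rep(0, arm$n_muscles),
                 upper = rep(1, arm$n_muscles),
                 f_max = arm$f_max,
                 arm = arm),
            class = "task_constraints")
}

# Rank-revealing solve of A x = b: minimum-norm particular solution,
# numerical rank, and an orthonormal null-space basis.
solve_affine <- function(A, b, rank_tol = NULL) {
  sv <- svd(A, nu = nrow(A), nv = ncol(A))
  if (is.null(rank_tol))
    rank_tol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > rank_tol)
  if (r == 0) {
    a0 <- rep(0, ncol(A))
  } else {
    a0 <- sv$v[, seq_len(r), drop = FALSE] %*%
      ((t(sv$u[, seq_len(r), drop = FALSE]) %*% b) / sv$d[seq_len(r)])
  }
  consistent <- max(abs(A %*% a0 - b)) <= 1e-8 * (1 + max(abs(b)))
  nullsp <- if (r < ncol(A)) sv$v[, (r + 1):ncol(A), drop = FALSE] else
    matrix(0, ncol(A), 0)
  list(a0 = as.numeric(a0), rank = r, null_basis = nullsp,
       consistent = consistent)
}

empty_segment <- function(null_dim = NA_integer_, reason = "infeasible") {
  structure(list(empty = TRUE, a0 = NULL, direction = NULL,
                 t_range = c(NA_real_, NA_real_), null_dim = null_dim,
                 degenerate = isTRUE(null_dim >= 2), reason = reason),
            class = "feasible_segment")
}

#' Exact feasible activation segment of a stiffness task
#'
#' Solves the equality system of a [task_constraints()] object and
#' intersects its affine solution set with the activation box. Generically
#' (6 muscles, 2 equilibrium + 3 stiffness constraints) the solution set is
#' a line, and the feasible activation set is the segment of that line
#' inside `[0, 1]^M`, parametrized as `a(t) = a0 + t * direction` with
#' `t` in `t_range`.
#'
#' If the null space has dimension 0 the feasible set is the single point
#' `a0` (when inside the box). Dimension >= 2 is flagged `degenerate`; such
#' polytopes are handled downstream by vertex enumeration / quadratic
#' programming rather than by the segment parametrization.
#'
#' @param tc a [task_constraints()] object.
#' @param box_tol slack allowed on the box bounds.
#' @param rank_tol singular-value cutoff for the numerical rank (default:
#'   SVD-based machine tolerance).
#' @param unbounded_above if `TRUE`, drop the upper activation bounds and
#'   intersect with the nonnegative orthant only (used for scale-free
#'   realizability tests; the feasible set is then possibly a ray).
#' @return An object of class `feasible_segment`: list with `empty`, `a0`,
#'   `direction` (unit vector, `NULL` unless the null space is 1-D),
#'   `t_range`, `null_dim`, `degenerate`, `null_basis`.
#' @export
feasible_segment <- function(tc, box_tol = 1e-9, rank_tol = NULL,
                             unbounded_above = FALSE) {
  stopifnot(inherits(tc, "task_constraints"))
  sol <- solve_affine(tc$A_eq, tc$b_eq, rank_tol)
  if (!sol$consistent)
    return(empty_segment(ncol(tc$A_eq) - sol$rank, "inconsistent equalities"))
  null_dim <- ncol(tc$A_eq) - sol$rank
  lower <- tc$lower
  upper <- if (unbounded_above) rep(Inf, length(tc$upper)) else tc$upper
  if (null_dim == 0) {
    inside <- all(sol$a0 >= lower - box_tol) && all(sol$a0 <= upper + box_tol)
    if (!inside) return(empty_segment(0L, "unique solution outside box"))
    return(structure(list(empty = FALSE, a0 = sol$a0, direction = NULL,
                          t_range = c(0, 0), null_dim = 0L,
                          degenerate = FALSE,
                          null_basis = sol$null_basis),
                     class = "feasible_segment"))
  }
  if (null_dim >= 2) {
    # Degenerate: report the affine piece; feasibility decided by callers
    # via vertex enumeration / QP.
    feas <- polytope_feasible_point(tc$A_eq, tc$b_eq, lower, upper, box_tol)
    if (is.null(feas)) return(empty_segment(null_dim, "empty polytope"))
    return(structure(list(empty = FALSE, a0 = feas, direction = NULL,
                          t_range = c(NA_real_, NA_real_),
                          null_dim = as.integer(null_dim), degenerate = TRUE,
                          null_basis = sol$null_basis),
                     class = "feasible_segment"))
  }
  d <- as.numeric(sol$null_basis[, 1])
  t_lo <- -Inf; t_hi <- Inf
  for (i in seq_along(d)) {
    if (abs(d[i]) < 1e-12) {
      if (sol$a0[i] < lower[i] - box_tol || sol$a0[i] > upper[i] + box_tol)
        return(empty_segment(1L, "line misses box"))
    } else {
      t1 <- (lower[i] - sol$a0[i]) / d[i]
      t2 <- (upper[i] - sol$a0[i]) / d[i]
      t_lo <- max(t_lo, min(t1, t2))
      t_hi <- min(t_hi, max(t1, t2))
    }
  }
  if (t_lo > t_hi + box_tol)
    return(empty_segment(1L, "line misses box"))
  structure(list(empty = FALSE, a0 = sol$a0, direction = d,
                 t_range = c(t_lo, t_hi), null_dim = 1L, degenerate = FALSE,
                 null_basis = sol$null_basis),
            class = "feasible_segment")
}

#' @export
print.feasible_segment <- function(x, ...) {
  if (x$empty) {
    cat("<feasible_segment> empty (", x$reason, ")\n", sep = "")
  } else if (x$degenerate) {
    cat("<feasible_segment> degenerate polytope, null dimension",
        x$null_dim, "\n")
  } else {
    cat(sprintf("<feasible_segment> null dimension %d, t in [%.6g, %.6g]\n",
                x$null_dim, x$t_range[1], x$t_range[2]))
  }
  invisible(x)
}

segment_point <- function(seg, t) {
  if (is.null(seg$direction)) seg$a0 else seg$a0 + t * seg$direction
}

# Feasible point of {A a = b, lower <= a <= upper} via QP (min ||a||^2),
# used only for degenerate (null dim >= 2) systems. Returns NULL if none.
polytope_feasible_point <- function(A, b, lower, upper, box_tol = 1e-9) {
  n <- ncol(A)
  a <- tryCatch(
    pracma::quadprog(diag(n), rep(0, n), Aeq = A, beq = b,
                     lb = lower, ub = upper)$xmin,
    error = function(e) NULL)
  if (is.null(a)) return(NULL)
  ok <- max(abs(A %*% a - b)) <= 1e-6 * (1 + max(abs(b))) &&
    all(a >= lower - 1e-6) && all(a <= upper + 1e-6)
  if (ok) pmin(upper, pmax(lower, a)) else NULL
}

# Vertices of {A a = b, 0 <= a <= 1}: fix (n - rank) coordinates at a bound,
# solve the rest. Combinatorial, fine for the small muscle counts here.
polytope_vertices <- function(A, b, lower, upper, rank_tol = NULL,
                              box_tol = 1e-8) {
  n <- ncol(A)
  sv <- svd(A)
  if (is.null(rank_tol))
    rank_tol <- max(dim(A)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > rank_tol)
  k <- n - r
  if (k <= 0) k <- 0
  verts <- list()
  idx_sets <- if (k == 0) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  for (fix in idx_sets) {
    free <- setdiff(seq_len(n), fix)
    assigns <- if (length(fix) == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(0, 1)), length(fix))))
    for (j in seq_len(nrow(assigns))) {
      a <- rep(NA_real_, n)
      a[fix] <- ifelse(assigns[j, ] == 0, lower[fix], upper[fix])
      rhs <- b - if (length(fix)) A[, fix, drop = FALSE] %*% a[fix] else 0
      Af <- A[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(Af, rhs, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      a[free] <- sol
      if (max(abs(A %*% a - b)) > 1e-7 * (1 + max(abs(b)))) next
      if (any(a < lower - box_tol) || any(a > upper + box_tol)) next
      verts[[length(verts) + 1]] <- pmin(upper, pmax(lower, a))
    }
  }
  if (length(verts) == 0) return(matrix(0, 0, n))
  V <- unique(round(do.call(rbind, verts), 10))
  V
}

segment_energy_coefs <- function(seg, f_max) {
  fa0 <- f_max * seg$a0
  fd <- f_max * seg$direction
  list(q2 = sum(fd^2), q1 = 2 * sum(fa0 * fd), q0 = sum(fa0^2))
}

activation_energy <- function(a, f_max) sum((f_max * a)^2)

#' Minimum-energy activation for a stiffness task
#'
#' Minimizes the metabolic-cost surrogate, the sum of squared muscle forces
#' `sum((f_max * a)^2)`, over the feasible activation set. On the generic
#' 1-D segment this is exact 1-D calculus (clamped parabola vertex); on
#' degenerate higher-dimensional polytopes a quadratic program is used.
#'
#' @param tc a [task_constraints()] object.
#' @param seg optionally a precomputed [feasible_segment()].
#' @return A list with `status` (`"ok"` or `"unrealizable"`), `activation`,
#'   and `energy`.
#' @export
min_energy <- function(tc, seg = feasible_segment(tc)) {
  if (seg$empty)
    return(list(status = "unrealizable", activation = NULL,
                energy = NA_real_))
  if (seg$null_dim == 0) {
    return(list(status = "ok", activation = seg$a0,
                energy = activation_energy(seg$a0, tc$f_max)))
  }
  if (seg$degenerate) {
    n <- length(tc$lower)
    a <- pracma::quadprog(2 * diag(tc$f_max^2), rep(0, n),
                          Aeq = tc$A_eq, beq = tc$b_eq,
                          lb = tc$lower, ub = tc$upper)$xmin
    a <- pmin(tc$upper, pmax(tc$lower, a))
    return(list(status = "ok", activation = a,
                energy = activation_energy(a, tc$f_max)))
  }
  q <- segment_energy_coefs(seg, tc$f_max)
  t_star <- if (q$q2 > 0) -q$q1 / (2 * q$q2) else seg$t_range[1]
  t_star <- min(seg$t_range[2], max(seg$t_range[1], t_star))
  a <- segment_point(seg, t_star)
  list(status = "ok", activation = a,
       energy = activation_energy(a, tc$f_max))
}

#' Maximum-energy activation for a stiffness task
#'
#' The energy is convex, so on the 1-D feasible segment its maximum is at a
#' segment endpoint; both endpoints are evaluated and the larger returned.
#' On degenerate polytopes the maximum is taken over the enumerated
#' vertices (a convex function on a polytope is maximized at a vertex).
#'
#' @inheritParams min_energy
#' @return As [min_energy()].
#' @export
max_energy <- function(tc, seg = feasible_segment(tc)) {
  if (seg$empty)
    return(list(status = "unrealizable", activation = NULL,
                energy = NA_real_))
  if (seg$null_dim == 0) {
    return(list(status = "ok", activation = seg$a0,
                energy = activation_energy(seg$a0, tc$f_max)))
  }
  if (seg$degenerate) {
    V <- polytope_vertices(tc$A_eq, tc$b_eq, tc$lower, tc$upper)
    if (nrow(V) == 0)
      return(list(status = "unrealizable", activation = NULL,
                  energy = NA_real_))
    en <- apply(V, 1, activation_energy, f_max = tc$f_max)
    i <- which.max(en)
    return(list(status = "ok", activation = V[i, ], energy = en[i]))
  }
  ends <- lapply(seg$t_range, function(t) segment_point(seg, t))
  en <- vapply(ends, activation_energy, numeric(1), f_max = tc$f_max)
  i <- which.max(en)
  list(status = "ok", activation = ends[[i]], energy = en[i])
}

#' Percent energy reduction between extreme feasible energies
#'
#' `100 * (e_max - e_min) / e_max`: the largest relative saving available to
#' the controller while holding the endpoint stiffness fixed. For example,
#' a maximal expenditure of 0.5 and a minimal expenditure of 0.35 leave a
#' maximum of 30 percent reduction.
#'
#' @param e_min,e_max minimal and maximal feasible energies,
#'   `0 <= e_min <= e_max`.
#' @return Percent in `[0, 100]`; `NA` when `e_max` is zero (undefined).
#' @export
energy_reduction_pct <- function(e_min, e_max) {
  if (any(e_min < 0) || any(e_max < e_min))
    stop("need 0 <= e_min <= e_max")
  ifelse(e_max > 0, 100 * (e_max - e_min) / e_max, NA_real_)
}

#' Energy range and achievable reduction for a stiffness task
#'
#' Computes the minimal and maximal energy over the feasible activation set
#' and the maximal relative reduction `100 * (e_max - e_min) / e_max` (in
#' percent): how much the controller can economize without changing the
#' endpoint stiffness.
#'
#' @inheritParams min_energy
#' @return A list with `status`, `e_min`, `e_max`, `reduction_pct`
#'   (`NA` with status `"zero_energy"` when `e_max == 0`).
#' @export
energy_range <- function(tc, seg = feasible_segment(tc)) {
  lo <- min_energy(tc, seg)
  if (lo$status != "ok")
    return(list(status = "unrealizable", e_min = NA_real_, e_max = NA_real_,
                reduction_pct = NA_real_))
  hi <- max_energy(tc, seg)
  if (hi$energy <= 0)
    return(list(status = "zero_energy", e_min = lo$energy,
                e_max = hi$energy, reduction_pct = NA_real_))
  list(status = "ok", e_min = lo$energy, e_max = hi$energy,
       reduction_pct = energy_reduction_pct(lo$energy, hi$energy))
}

#' Monte-Carlo bracket of the feasible energies (verification oracle)
#'
#' Samples activations uniformly along the feasible segment and returns the
#' extreme sampled energies. Independent of the closed-form extremization;
#' used as a bracketing check: sampled extremes always lie within
#' `[e_min, e_max]`.
#'
#' @inheritParams min_energy
#' @param n_samples number of uniform samples of the segment parameter.
#' @param seed integer seed (local RNG, does not disturb the global state).
#' @return A list with `min`, `max` sampled energies.
#' @export
oracle_energy_bracket <- function(tc, n_samples = 1000, seed = 1,
                                  seg = feasible_segment(tc)) {
  if (seg$empty) stop("task is unrealizable; nothing to sample")
  if (seg$degenerate) stop("bracketing oracle requires a 1-D segment")
  ts <- withr_seed(seed, stats::runif(n_samples, seg$t_range[1],
                                      seg$t_range[2]))
  en <- vapply(ts, function(t)
    activation_energy(segment_point(seg, t), tc$f_max), numeric(1))
  list(min = min(en), max = max(en))
}

# Evaluate expr under a local RNG seed, restoring the global state.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Is a desired stiffness ellipse realizable at a posture?
#'
#' Tests whether some activation in `[0, 1]^M` satisfies torque equilibrium
#' and produces an endpoint stiffness with the given shape and orientation.
#' With `scale = "auto"` the test is scale-free: it asks whether the ellipse
#' is realizable at *some* positive size, which by homogeneity reduces to
#' intersecting the equality solution set with the nonnegative orthant (any
#' nonnegative solution can be scaled below the activation ceiling). With a
#' numeric `scale` the exact box-bounded test at that size is used.
#'
#' @param arm an [arm_model()] with two joints.
#' @param theta joint angles (radians).
#' @param shape condition number (>= 1) of the desired ellipse.
#' @param orientation_deg desired major-axis angle (degrees).
#' @param scale `"auto"` for the scale-free test, or a positive number.
#' @return Logical.
#' @export
is_realizable <- function(arm, theta, shape, orientation_deg,
                          scale = "auto") {
  if (identical(scale, "auto")) {
    tc <- task_constraints(arm, theta,
                           desired_stiffness(shape, orientation_deg, 1))
    seg <- feasible_segment(tc, unbounded_above = TRUE)
    return(!seg$empty)
  }
  tc <- task_constraints(arm, theta,
                         desired_stiffness(shape, orientation_deg, scale))
  !feasible_segment(tc)$empty
}

#' Choose a desired-stiffness scale clear of activation saturation
#'
#' For a realizable (shape, orientation) at a posture, returns a scale such
#' that the feasible activation segment sits well inside the activation box
#' (maximum activation about `target_max` at the segment endpoints), so the
#' upper activation bounds are inactive and energy-reduction ratios are
#' scale-invariant. Returns `NA` if the task is unrealizable at any scale.
#'
#' @inheritParams is_realizable
#' @param target_max largest activation allowed at the scaled segment's
#'   endpoints (default 0.5).
#' @return A positive scale, or `NA_real_`.
#' @export
auto_scale <- function(arm, theta, shape, orientation_deg,
                       target_max = 0.5) {
  tc <- task_constraints(arm, theta,
                         desired_stiffness(shape, orientation_deg, 1))
  seg <- feasible_segment(tc, unbounded_above = TRUE)
  if (seg$empty) return(NA_real_)
  if (seg$degenerate) {
    m <- max(seg$a0)
    return(if (m <= 0) 1 else target_max / m)
  }
  ts <- seg$t_range[is.finite(seg$t_range)]
  if (length(ts) == 0) ts <- 0
  m <- max(vapply(ts, function(t) max(segment_point(seg, t)), numeric(1)))
  if (m <= 0) 1 else target_max / m
}

#' Fraction of realizable ellipse orientations at a posture
#'
#' Tests the desired ellipse at orientations `0, step, 2*step, ...` degrees
#' over the 180-degree half-circle and returns the fraction that are
#' realizable.
#'
#' @inheritParams is_realizable
#' @param step orientation grid step in degrees; must divide 180.
#' @return Fraction in `[0, 1]`.
#' @export
realizable_fraction <- function(arm, theta, shape, scale = "auto",
                                step = 5) {
  if (180 %% step != 0) stop("step must divide 180 degrees")
  phis <- seq(0, 180 - step, by = step)
  mean(vapply(phis, function(p)
    is_realizable(arm, theta, shape, p, scale), logical(1)))
}
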