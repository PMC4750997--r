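#' Construct a muscle synergy basis
#'
#' A synergy basis is a nonnegative muscles x synergies weight matrix `W`.
#' Muscle activations on the synergy manifold are `a = W %*% c` for
#' nonnegative synergy commands `c`; synergies couple muscles and thereby
#' remove independent control degrees of freedom.
#'
#' @param W nonnegative numeric matrix, muscles x synergies, no zero
#'   columns, fewer synergies than muscles.
#' @param names optional synergy labels.
#' @return An object of class `synergy_basis`.
#' @export
synergy_basis <- function(W, names = NULL) {
  W <- as.matrix(W)
  if (any(!is.finite(W)) || any(W < 0))
    stop("synergy weights must be finite and nonnegative")
  if (any(colSums(W) == 0)) stop("every synergy column must be nonzero")
  if (ncol(W) >= nrow(W))
    stop("a synergy basis must have fewer synergies than muscles")
  if (is.null(names)) names <- paste0("synergy", seq_len(ncol(W)))
  colnames(W) <- names
  structure(list(W = W, names = names), class = "synergy_basis")
}

#' @export
print.synergy_basis <- function(x, ...) {
  cat("<synergy_basis>:", nrow(x$W), "muscles x", ncol(x$W), "synergies\n")
  print(x$W)
  invisible(x)
}

#' The two-synergy shoulder/elbow basis of Osu and Gomi
#'
#' Weights from the EMG co-contraction study of Osu and Gomi on static arm
#' postures: the shoulder synergy drives the two mono-articular shoulder
#' muscles with unit weight; the elbow synergy drives the two mono-articular
#' elbow muscles with unit weight and both bi-articular muscles with weight
#' one-half (their bi-articular co-contraction contributed about half the
#' elbow stiffness of the mono-articular elbow muscles). Muscle order
#' matches [default_arm()].
#'
#' @return A [synergy_basis()] with columns `shoulder`, `elbow`.
#' @export
osu_gomi_basis <- function() {
  synergy_basis(cbind(c(1, 1, 0, 0, 0, 0),
                      c(0, 0, 1, 1, 0.5, 0.5)),
                names = c("shoulder", "elbow"))
}

#' Muscle activation produced by synergy commands
#'
#' @param basis a [synergy_basis()].
#' @param c nonnegative synergy command vector (one entry per synergy).
#' @return Muscle activation vector `W %*% c`, validated against the
#'   `[0, 1]` activation bounds.
#' @export
synergy_activation <- function(basis, c) {
  stopifnot(inherits(basis, "synergy_basis"))
  c <- as.numeric(c)
  if (length(c) != ncol(basis$W) || any(!is.finite(c)) || any(c < 0))
    stop("synergy commands must be ", ncol(basis$W),
         " nonnegative finite values")
  a <- as.numeric(basis$W %*% c)
  over <- which(a > 1 + 1e-9)
  if (length(over))
    stop("synergy command saturates muscle(s) ",
         paste(over, collapse = ", "), " (activation > 1)")
  pmin(1, pmax(0, a))
}

#' Sweep the elbow/shoulder synergy activation ratio
#'
#' On the two-synergy manifold one free parameter, the ratio of elbow to
#' shoulder synergy activation, controls the shape and orientation of the
#' endpoint-stiffness ellipse; scaling both commands together changes only
#' its size. This sweeps that ratio and records the ellipse at each value.
#' Commands are normalized to `c_shoulder + c_elbow = base_total`; if a
#' command would saturate a muscle, both are scaled down (with a message),
#' which leaves shape and orientation unchanged.
#'
#' @param arm an [arm_model()] with two joints (muscle count matching the
#'   basis).
#' @param theta joint angles (radians), non-singular.
#' @param basis a two-column [synergy_basis()] (default [osu_gomi_basis()]).
#' @param ratios positive ratios `c_elbow / c_shoulder` to sweep; default
#'   200 log-spaced values in `[0.1, 10]`.
#' @param base_total total synergy command `c_shoulder + c_elbow`
#'   (default 0.5).
#' @return A data frame with columns `ratio`, `size`, `area`, `shape`,
#'   `orientation` (degrees, `NA` when isotropic).
#' @export
ratio_sweep <- function(arm, theta, basis = osu_gomi_basis(),
                        ratios = log_ratios(), base_total = 0.5) {
  stopifnot(inherits(basis, "synergy_basis"), ncol(basis$W) == 2)
  if (any(ratios <= 0)) stop("ratios must be positive")
  rows <- lapply(ratios, function(r) {
    cs <- base_total / (1 + r)
    cc <- c(cs, r * cs)
    amax <- max(basis$W %*% cc)
    if (amax > 1) {
      message(sprintf(
        "ratio %.4g saturates a muscle; commands scaled by %.4g", r,
        0.99 / amax))
      cc <- cc * 0.99 / amax
    }
    a <- synergy_activation(basis, cc)
    ell <- stiffness_ellipse(endpoint_stiffness(arm, theta, a))
    data.frame(ratio = r, size = ell$size, area = ell$area,
               shape = ell$shape, orientation = ell$orientation)
  })
  do.call(rbind, rows)
}

#' Default log-spaced ratio grid
#'
#' @param n number of points (default 200).
#' @param range two positive endpoints (default `c(0.1, 10)`).
#' @return Numeric vector of `n` log-spaced ratios.
#' @export
log_ratios <- function(n = 200, range = c(0.1, 10)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Circular range of ellipse orientations on the 180-degree axis
#'
#' Ellipse orientations live on a 180-degree-periodic circle. The range of a
#' set of orientations is 180 degrees minus the largest empty arc between
#' consecutive (sorted, wrapped) orientations — the smallest arc covering all
#' of them.
#'
#' @param orientations numeric vector of orientations in degrees, or a
#'   [ratio_sweep()] result (its `orientation` column is used). `NA`s
#'   (isotropic points) are dropped.
#' @return A list with `range_deg` and `fraction` (`range_deg / 180`).
#' @export
orientation_range <- function(orientations) {
  if (is.data.frame(orientations)) orientations <- orientations$orientation
  phi <- sort(orientations[!is.na(orientations)] %% 180)
  if (length(phi) == 0)
    stop("no defined orientations (all isotropic)")
  if (length(phi) == 1)
    return(list(range_deg = 0, fraction = 0))
  gaps <- c(diff(phi), phi[1] + 180 - phi[length(phi)])
  rng <- 180 - max(gaps)
  list(range_deg = rng, fraction = rng / 180)
}

#' Realizability of a desired stiffness under a synergy constraint
#'
#' Substitutes `a = W %*% c` into the task's equality constraints and tests
#' feasibility in synergy-command space: `(A_eq %*% W) %*% c = b_eq` with
#' `c >= 0` and `0 <= W %*% c <= 1`. Reports the dimension of the solution
#' space in command space; synergies generically reduce it (often to zero, a
#' unique solution) or overconstrain the task entirely.
#'
#' @param arm an [arm_model()].
#' @param theta joint angles (radians); ignored for single-joint limbs.
#' @param desired desired vectorized stiffness (see [task_constraints()]).
#' @param basis a [synergy_basis()] with rows matching the arm's muscles.
#'   The muscles x muscles identity is accepted as the "no synergy" sentinel
#'   (pass `W = diag(M)` via `identity_basis()`), in which case the result
#'   coincides with the unconstrained test.
#' @return A list with `realizable` (logical), `solution_dim` (dimension of
#'   the feasible set in command space; `NA` when unrealizable), `c`
#'   (a feasible command, when one exists), `activation`.
#' @export
constrained_realizability <- function(arm, theta = NULL, desired, basis) {
  W <- if (inherits(basis, "synergy_basis")) basis$W else as.matrix(basis)
  if (nrow(W) != arm$n_muscles)
    stop("basis rows must match the arm's muscle count")
  tc <- task_constraints(arm, theta, desired)
  Ac <- tc$A_eq %*% W
  sol <- solve_affine(Ac, tc$b_eq)
  if (!sol$consistent)
    return(list(realizable = FALSE, solution_dim = NA_integer_,
                c = NULL, activation = NULL))
  null_dim <- ncol(Ac) - sol$rank
  # inequalities in command space: c >= 0, 0 <= W c <= 1
  G <- rbind(diag(ncol(W)), W, -W)
  h_lo_ok <- function(cc) all(G[seq_len(ncol(W)), , drop = FALSE] %*% cc >=
                                -1e-9)
  feas <- function(cc) {
    a <- W %*% cc
    all(cc >= -1e-9) && all(a >= -1e-9) && all(a <= 1 + 1e-9)
  }
  if (null_dim == 0) {
    ok <- feas(sol$a0)
    return(list(realizable = ok,
                solution_dim = if (ok) 0L else NA_integer_,
                c = if (ok) pmax(0, sol$a0) else NULL,
                activation = if (ok)
                  as.numeric(W %*% pmax(0, sol$a0)) else NULL))
  }
  if (null_dim == 1) {
    d <- as.numeric(sol$null_basis[, 1])
    # 1-D: intersect line with all inequalities
    t_lo <- -Inf; t_hi <- Inf
    cons_a <- rbind(diag(ncol(W)), W)       # >= 0 rows
    cons_b <- W                             # <= 1 rows
    for (i in seq_len(nrow(cons_a))) {
      g <- sum(cons_a[i, ] * d); v <- sum(cons_a[i, ] * sol$a0)
      if (abs(g) < 1e-12) { if (v < -1e-9) t_lo <- Inf }
      else if (g > 0) t_lo <- max(t_lo, -v / g)
      else t_hi <- min(t_hi, -v / g)
    }
    for (i in seq_len(nrow(cons_b))) {
      g <- sum(cons_b[i, ] * d); v <- sum(cons_b[i, ] * sol$a0)
      if (abs(g) < 1e-12) { if (v > 1 + 1e-9) t_lo <- Inf }
      else if (g > 0) t_hi <- min(t_hi, (1 - v) / g)
      else t_lo <- max(t_lo, (1 - v) / g)
    }
    if (t_lo > t_hi + 1e-9)
      return(list(realizable = FALSE, solution_dim = NA_integer_,
                  c = NULL, activation = NULL))
    t_mid <- if (is.finite(t_lo) && is.finite(t_hi)) (t_lo + t_hi) / 2
    else if (is.finite(t_lo)) t_lo else min(t_hi, 0)
    cc <- sol$a0 + t_mid * d
    return(list(realizable = TRUE, solution_dim = 1L, c = pmax(0, cc),
                activation = as.numeric(W %*% pmax(0, cc))))
  }
  # higher-dimensional command space: QP feasibility
  cc <- tryCatch(
    pracma::quadprog(diag(ncol(W)), rep(0, ncol(W)),
                     A = rbind(-diag(ncol(W)), -W, W),
                     b = c(rep(0, ncol(W) + nrow(W)), rep(1, nrow(W))),
                     Aeq = Ac, beq = tc$b_eq)$xmin,
    error = function(e) NULL)
  ok <- !is.null(cc) && feas(cc) &&
    max(abs(Ac %*% cc - tc$b_eq)) <= 1e-6 * (1 + max(abs(tc$b_eq)))
  list(realizable = ok,
       solution_dim = if (ok) as.integer(null_dim) else NA_integer_,
       c = if (ok) pmax(0, cc) else NULL,
       activation = if (ok) as.numeric(W %*% pmax(0, cc)) else NULL)
}

#' Identity (no-synergy) sentinel basis
#'
#' @param n_muscles number of muscles.
#' @return The muscles x muscles identity matrix (not a `synergy_basis`,
#'   since it removes no degrees of freedom); accepted by
#'   [constrained_realizability()] as the unconstrained sentinel.
#' @export
identity_basis <- function(n_muscles) diag(n_muscles)
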