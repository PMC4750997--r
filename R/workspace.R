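workspace_map <- function(records, kind, shape = NA_real_, grid = NULL,
                          arm = NULL, extra = list()) {
  df <- do.call(rbind, records)
  rownames(df) <- NULL
  structure(df, kind = kind, shape = shape, grid = grid,
            arm_summary = if (!is.null(arm))
              list(n_muscles = arm$n_muscles,
                   link_lengths = arm$link_lengths,
                   alpha = arm$alpha, f_max = arm$f_max) else NULL,
            extra = extra,
            class = c("workspace_map", class(df)))
}

map_record <- function(theta, xy, value, status) {
  data.frame(theta1 = theta[1], theta2 = theta[2],
             endpoint_x = xy[1], endpoint_y = xy[2],
             value = value, status = status)
}

#' Map of realizable-orientation fractions over the workspace
#'
#' For each non-singular posture on a joint-angle grid, computes the
#' fraction of ellipse orientations (every `step` degrees over 180) that
#' are realizable at the given ellipse shape (condition number).
#'
#' @param arm an [arm_model()] with two joints.
#' @param shape ellipse condition number (> 1 so orientation is meaningful).
#' @param n1,n2 grid counts over the joint limits (default 25 x 25).
#' @param step orientation grid step in degrees.
#' @param scale `"auto"` (scale-free realizability) or a positive number.
#' @return A `workspace_map` data frame with columns `theta1`, `theta2`
#'   (radians), `endpoint_x`, `endpoint_y`, `value` (fraction), `status`.
#' @export
realizable_fraction_map <- function(arm, shape, n1 = 25, n2 = 25, step = 5,
                                    scale = "auto") {
  if (shape <= 1) stop("shape must exceed 1 for an orientation map")
  grid <- posture_grid(arm, n1, n2)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid[i, ]
    map_record(th, forward_kinematics(arm, th),
               realizable_fraction(arm, th, shape, scale, step), "ok")
  })
  workspace_map(recs, "realizable_fraction", shape,
                grid = c(n1 = n1, n2 = n2, step = step), arm = arm)
}

#' Map of maximal achievable energy reduction over the workspace
#'
#' For each grid posture, takes the maximum over realizable orientations of
#' the percent energy reduction `100 * (e_max - e_min) / e_max` for the
#' desired ellipse shape. Per-orientation desired-stiffness sizes are
#' auto-scaled below activation saturation (the reduction ratio is invariant
#' to that scale). Postures where no orientation is realizable get status
#' `"unrealizable"`; postures where the feasible set leaves no room to
#' economize (single-point segments everywhere) report 0.
#'
#' @inheritParams realizable_fraction_map
#' @return A `workspace_map` with `value` = max reduction percent (`NA` when
#'   unrealizable).
#' @export
energy_reduction_map <- function(arm, shape, n1 = 25, n2 = 25, step = 5) {
  grid <- posture_grid(arm, n1, n2)
  phis <- seq(0, 180 - step, by = step)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid[i, ]
    best <- NA_real_
    for (p in phis) {
      red <- orientation_reduction(arm, th, shape, p)
      if (!is.na(red)) best <- max(best, red, na.rm = TRUE)
    }
    map_record(th, forward_kinematics(arm, th), best,
               if (is.na(best)) "unrealizable" else "ok")
  })
  workspace_map(recs, "energy_reduction", shape,
                grid = c(n1 = n1, n2 = n2, step = step), arm = arm)
}

# Reduction percent for one (posture, shape, orientation); NA when
# unrealizable. The desired size is auto-scaled below saturation.
orientation_reduction <- function(arm, theta, shape, orientation_deg) {
  s <- auto_scale(arm, theta, shape, orientation_deg)
  if (is.na(s)) return(NA_real_)
  tc <- task_constraints(arm, theta,
                         desired_stiffness(shape, orientation_deg, s))
  er <- energy_range(tc)
  if (er$status != "ok") return(NA_real_)
  er$reduction_pct
}

#' Map of synergy-constrained orientation fractions over the workspace
#'
#' For each grid posture, sweeps the synergy activation ratio and reports
#' the circular orientation range achieved on the synergy manifold as a
#' fraction of 180 degrees — the synergy-constrained analogue of
#' [realizable_fraction_map()].
#'
#' @inheritParams realizable_fraction_map
#' @param basis a two-column [synergy_basis()].
#' @param ratios ratio grid for the sweep (default [log_ratios()]).
#' @return A `workspace_map` with `value` = orientation range / 180.
#' @export
synergy_fraction_map <- function(arm, basis = osu_gomi_basis(),
                                 n1 = 25, n2 = 25, ratios = log_ratios()) {
  grid <- posture_grid(arm, n1, n2)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid[i, ]
    sw <- ratio_sweep(arm, th, basis, ratios)
    val <- tryCatch(orientation_range(sw)$fraction,
                    error = function(e) NA_real_)
    map_record(th, forward_kinematics(arm, th), val,
               if (is.na(val)) "isotropic" else "ok")
  })
  workspace_map(recs, "synergy_fraction", NA_real_,
                grid = c(n1 = n1, n2 = n2, n_ratios = length(ratios)),
                arm = arm)
}

#' Summary statistics of a workspace map
#'
#' @param object a `workspace_map`.
#' @param ... unused.
#' @return A list with `kind`, `n_postures`, `n_ok`, `mean_value`,
#'   `max_value`, `min_value` over postures with status `"ok"`.
#' @export
summary.workspace_map <- function(object, ...) {
  ok <- object$status == "ok" & !is.na(object$value)
  list(kind = attr(object, "kind"),
       shape = attr(object, "shape"),
       n_postures = nrow(object),
       n_ok = sum(ok),
       mean_value = if (any(ok)) mean(object$value[ok]) else NA_real_,
       max_value = if (any(ok)) max(object$value[ok]) else NA_real_,
       min_value = if (any(ok)) min(object$value[ok]) else NA_real_)
}
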